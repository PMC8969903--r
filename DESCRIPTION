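Package: gliotyper
Title: Molecular Interpretation of Targeted DNA Sequencing Panels for Diffuse Glioma
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Tumor-only interpretation of a targeted amplicon DNA panel for
    adult diffuse gliomas. Filters somatic variant calls by allele frequency,
    depth, quality and caller p-value with hotspot rescue; calls arm-level
    loss of heterozygosity (1p/19q co-deletion, the +7/-10 glioblastoma
    signature) from SNP B-allele frequencies; estimates gene-level copy
    number from baseline-normalized amplicon coverage gated by the MAPD
    noise metric; quantifies MGMT promoter methylation from bisulfite read
    counts at four CpG sites; scores FISH nucleus tallies with standard
    diagnostic thresholds; combines marker states into a WHO-CNS5-style
    integrated diagnosis with an actionability report; and computes the
    diagnostic concordance statistics (Cohen's kappa, sensitivity,
    specificity, allele-frequency regression) used to validate such panels.
    Includes read-count-level synthetic data generators with known truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
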