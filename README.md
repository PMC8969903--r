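# gliotyper

Molecular interpretation of targeted DNA sequencing panels for adult
diffuse glioma.

Since the 2021 WHO classification of CNS tumors, diagnosing a diffuse
glioma requires molecular markers alongside histology: IDH1/IDH2 mutation,
1p/19q co-deletion, ATRX loss, TERT promoter mutation, EGFR amplification,
the chromosome 7 gain / chromosome 10 loss (+7/−10) signature, CDKN2A/B
homozygous deletion, H3-3A K27M, and MGMT promoter methylation for
treatment decisions. A single targeted amplicon panel can measure all of
these at once — if every assay's raw output is interpreted with explicit,
reproducible rules. `gliotyper` implements that interpretation layer for
tumor-only sequencing, plus the FISH scoring rules used as the orthogonal
comparator and the concordance statistics used to validate a panel against
conventional testing. It is aimed at molecular pathology and
neuro-oncology bioinformatics groups running (or validating) such panels.

## What it computes

**Variant filtering.** A call is reportable when VAF ≥ 3% (clinically
established hotspots such as BRAF V600E, IDH1 R132, TERT c.1-124/−146 and
H3-3A K27M are rescued down to 2%), depth > 100, Phred quality > 40 and
caller p < 10⁻⁴; pathogenicity follows curated tiers 1–3. Gene marker
states (IDH canonical R132H vs non-canonical, ATRX truncating, TP53
missense vs nonsense, H3 K27M, TERT C228T/C250T) are derived from the
retained calls.

**SNP-BAF LOH.** For each panel SNP the B-allele frequency
b = alt/(ref+alt) is classified by windows: homozygous in [0, 0.05] ∪
[0.95, 1], balanced heterozygous in [0.45, 0.60], otherwise imbalanced —
the signature of allelic loss diluted by purity *a*, where a heterozygous
SNP under monoallelic loss sits at (1−a)/(2−a) or 1/(2−a). An arm is
called LOH when ≥ 5 informative (balanced+imbalanced) SNPs are present and
≥ 60% of them are imbalanced; 1p+19q LOH gives the co-deletion, and
chr7/chr10 imbalance oriented by the median coverage log2 ratio (> +0.1
gain, < −0.1 loss) gives the +7/−10 signature.

**Copy number.** Amplicon counts are library-size normalized against a
baseline of CNA-free samples; sample noise is gated by
MAPD = median |log2r(i) − log2r(i+1)| < 0.45. A gene's copy number is
CN = 2·2^(median log2 ratio); CN > 4 amplification, CN < 0.5 homozygous
deletion, with single-copy steps between, and a −10·log₁₀(p) confidence
filtered below 30.

**MGMT methylation.** The methylated fraction at the four CpG cytosines of
the assayed promoter 19-mer (chr10:131,265,519–131,265,537, hg19) is
averaged and banded: < 10% unmethylated, 10–50% moderate, > 50% high;
bisulfite conversion is QC'd on non-CpG cytosines. Sanger peak-ratio
scoring (methylated when C/(C+T) > 20%) is emulated for cross-method
comparison.

**FISH scoring.** Published thresholds on nucleus tallies: 1p/19q
co-deletion (≥ 30% 1O/2G nuclei and overall orange/green ratio ≤ 0.70 on
both probe sets), EGFR amplification (> 10% nuclei with ratio > 2 or
clusters), chromosome 7 gain / 10 loss (≥ 30% 3O/3G, 1O/1G), CDKN2A
homozygous deletion (≥ 20% 0O/≥1G); ≥ 200 nuclei required.

**Integration & validation.** Marker states combine into a WHO-CNS5-style
label (diffuse midline glioma → oligodendroglioma → astrocytoma →
IDH-wildtype glioblastoma → not-classifiable) with a rule trace and
caveats, plus a clinical-trial actionability report. Validation statistics
are Cohen's κ with interpretation bands (< 0.4 weak, 0.4–0.8 moderate,
≥ 0.8 strong), sensitivity/specificity in both reference directions, and
expected-vs-measured allele-frequency regression. A synthetic-data module
generates read-count-level inputs with known truth for every assay.

## Worked example

A synthetic IDH-wildtype glioblastoma (purity 0.6, +7/−10, EGFR at 20
copies, TERT C228T, methylated MGMT), interpreted end to end:

```r
library(gliotyper)
panel <- synthetic_panel()
tr <- truth_spec(sample_id = "GBM1", purity = 0.6,
  region_states = c(`1p` = "diploid", `19q` = "diploid",
                    chr7 = "gain", chr10 = "monoallelic-loss"),
  gene_cn = c(EGFR = 20), mgmt_methylation = 0.65)
variants <- variant_table(data.frame(chrom = "chr5", pos = 1295228,
  ref = "G", alt = "A", vaf = 0.30, depth = 700, quality = 80,
  pvalue = 1e-8, gene = "TERT", hgvs_c = "c.1-124C>T", tier = "1"))
bl <- build_baseline(vapply(1:10, function(j)
  simulate_coverage(truth_spec(purity = 0), panel, 500, 0.1, seed = 600 + j),
  numeric(nrow(panel$amplicons))), panel)
rep <- interpret_sample(panel, variants = variants,
  snp_counts = simulate_snp_counts(tr, panel, depth = 500, seed = 601),
  coverage = simulate_coverage(tr, panel, 500, 0.1, seed = 602),
  baseline = bl, bisulfite = simulate_bisulfite_counts(tr, 800, seed = 603),
  sample_id = "GBM1")
summary(rep)
```

```
== sample GBM1 ==
  idh            wild-type
  codeletion     not-codeleted
  atrx           wild-type
  tert           mutant
  egfr           amplification
  plus7_minus10  present
  cdkn2a         neutral
  h3             wild-type
  tp53           none
  mgmt           high
integrated diagnosis: glioblastoma, IDH-wildtype
  - rule-4: IDH wild-type + TERT promoter mutant + EGFR amplified + +7/-10 signature
actionable: TRUE (1 qualifying alteration, 1 trial match)
  gene    alteration         class                   agent combination
1 EGFR amplification amplification Afatinib or Osimertinib           -
        trial
1 NCT02465060
```

The per-assay details are in the report too — for instance
`print(rep$cna$calls$EGFR)` gives
`EGFR: CN 11.83 (amplification), median log2 2.565 over 30 amplicons,
confidence 3000.0` (truth: mixture CN 0.6·20 + 0.4·2 = 12.8), and
`print(rep$mgmt)` gives `MGMT promoter methylation: 66.3% (high)` with the
four per-site fractions and a conversion efficiency of 0.988.

## Command-line interface

`inst/cli/gliotyper.R` wraps the package functions as subcommands
(`filter-variants`, `call-loh`, `call-cna`, `call-mgmt`, `score-fish`,
`concordance`), reading the documented tab-separated/VCF/BED dialects and
writing JSON. `--config cfg.json` overrides any threshold; defaults are
the validated operating points above.
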