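#' Default pipeline configuration
#'
#' All thresholds used by the interpretation pipeline, grouped by assay.
#' The defaults are the validated operating points of the panel:
#' variant retention at VAF >= 3\% (hotspot rescue down to 2\%), read depth
#' > 100, Phred quality > 40, caller p-value < 1e-4; B-allele-frequency
#' homozygosity windows 0-5\% and 95-100\% with a 45-60\% heterozygosity
#' window; arm-level imbalance requiring >= 5 informative SNPs with >= 60\%
#' imbalanced; MAPD < 0.45 to admit a sample for copy-number analysis and a
#' confidence gate of 30 (i.e. p < 1e-3) on gene calls; MGMT methylation
#' bands at 10\% and 50\%; FISH thresholds of 30\% diagnostic nuclei with an
#' orange/green ratio <= 0.70 for arm loss, > 10\% high-ratio nuclei
#' (ratio > 2) for EGFR amplification, and 20\% empty-orange nuclei for
#' CDKN2A homozygous deletion.
#'
#' @return a `gliotyper_config` list with components `variant`, `baf`, `arm`,
#'   `direction`, `cna`, `methylation` and `fish`.
#' @export
default_config <- function() {
  structure(list(
    variant = list(
      min_vaf = 0.03,
      min_depth = 100,          # strict >
      min_quality = 40,         # strict >
      max_pvalue = 0.0001,      # strict <
      pathogenic_tiers = c("1", "2", "3"),
      hotspot_rescue_vaf = 0.02
    ),
    baf = list(
      hom_low = c(0, 0.05),
      hom_high = c(0.95, 1),
      het = c(0.45, 0.60),
      min_depth = 100
    ),
    arm = list(
      min_informative = 5,
      min_fraction = 0.6
    ),
    direction = list(
      gain_log2 = 0.1,
      loss_log2 = -0.1
    ),
    cna = list(
      mapd_max = 0.45,          # strict <
      min_confidence = 30,
      baseline_min_samples = 2,
      baseline_expected_samples = 10,
      epsilon_reads = 1,
      cn_amplification = 4,     # CN > 4
      cn_gain = 2.5,            # 2.5 < CN <= 4
      cn_neutral_low = 1.5,     # 1.5 <= CN <= 2.5
      cn_loss = 0.5             # 0.5 <= CN < 1.5; below: homozygous deletion
    ),
    methylation = list(
      unmethylated_below = 10,  # percent, strict <
      high_above = 50,          # percent, strict >
      conversion_floor = 0.98,
      sanger_cutoff = 0.20      # strict > for methylated
    ),
    fish = list(
      min_nuclei = 200,
      codeletion_fraction = 0.30,  # >= 30% nuclei 1O/2G
      codeletion_ratio = 0.70,     # overall ratio <= 0.70
      amplification_fraction = 0.10, # > 10% nuclei ratio > 2 or clusters
      amplification_ratio = 2,
      chromosome_fraction = 0.30,  # >= 30% nuclei 3O/3G (chr7) / 1O/1G (chr10)
      cdkn2a_fraction = 0.20       # >= 20% nuclei 0O/>=1G
    )
  ), class = "gliotyper_config")
}

#' Write a configuration to JSON
#'
#' @param config a `gliotyper_config` list.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a configuration from JSON, filling unspecified values with defaults
#'
#' Values present in the file override the defaults; anything omitted keeps
#' its default, so a config file need only name the thresholds it changes.
#'
#' @param path JSON file as written by [write_config()], possibly partial.
#' @return a `gliotyper_config` list.
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  for (grp in intersect(names(user), names(cfg))) {
    for (key in intersect(names(user[[grp]]), names(cfg[[grp]]))) {
      cfg[[grp]][[key]] <- user[[grp]][[key]]
    }
  }
  cfg
}

#' @export
print.gliotyper_config <- function(x, ...) {
  cat("gliotyper configuration\n")
  for (grp in names(x)) {
    cat(" ", grp, ":\n", sep = "")
    for (key in names(x[[grp]])) {
      cat("    ", key, " = ", paste(x[[grp]][[key]], collapse = ", "),
          "\n", sep = "")
    }
  }
  invisible(x)
}
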