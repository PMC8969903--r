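#' Read a FISH nucleus tally table
#'
#' Tab-separated with columns `nucleus`, `probe_set`, `orange`, `green`
#' and optional logical/0-1 `cluster` (innumerable orange clusters).
#'
#' @param path input TSV.
#' @return a data.frame of tallies.
#' @export
read_fish_tallies <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need_cols(df, c("nucleus", "probe_set", "orange", "green"), "FISH tally table")
  if (!"cluster" %in% names(df)) df$cluster <- FALSE
  df$cluster <- as.logical(df$cluster)
  df
}

fish_qc <- function(tallies, config) {
  n <- nrow(tallies)
  list(n_nuclei = n,
       n_zero_green = sum(tallies$green == 0),  # excluded from ratios
       valid = n >= config$fish$min_nuclei)
}

overall_ratio <- function(tallies) {
  keep <- tallies$green > 0
  if (!any(keep)) return(NA_real_)
  sum(tallies$orange[keep]) / sum(tallies$green[keep])
}

fish_result <- function(assay, verdict, fraction, ratio, qc) {
  structure(list(assay = assay, verdict = verdict,
                 diagnostic_fraction = fraction, ratio = ratio, qc = qc),
            class = "fish_result")
}

#' @export
print.fish_result <- function(x, ...) {
  cat(sprintf("FISH %s: %s (diagnostic nuclei %s, ratio %s, n=%d)\n",
              x$assay, x$verdict,
              ifelse(is.na(x$diagnostic_fraction), "NA",
                     sprintf("%.1f%%", 100 * x$diagnostic_fraction)),
              ifelse(is.na(x$ratio), "NA", sprintf("%.2f", x$ratio)),
              x$qc$n_nuclei))
  invisible(x)
}

#' Score 1p/19q co-deletion from FISH tallies
#'
#' A sample is co-deleted when, for each of the 1p36/1q25 and 19q13/19p13
#' probe sets, at least 30\% of neoplastic nuclei show the 1 orange /
#' 2 green deletion pattern and the overall orange/green ratio is <= 0.70.
#' Fewer than 200 nuclei on either probe set makes the assay not-evaluable.
#'
#' @param tallies_1p,tallies_19q tally data.frames (one probe set each).
#' @param config a `gliotyper_config`.
#' @return a `fish_result` with verdict `codeleted`/`not-codeleted`/
#'   `not-evaluable`; per-arm detail in `$arms`.
#' @export
score_1p19q <- function(tallies_1p, tallies_19q, config = default_config()) {
  score_one <- function(t) {
    qc <- fish_qc(t, config)
    frac <- mean(t$orange == 1 & t$green == 2)
    ratio <- overall_ratio(t)
    positive <- qc$valid && frac >= config$fish$codeletion_fraction &&
      !is.na(ratio) && ratio <= config$fish$codeletion_ratio
    list(qc = qc, fraction = frac, ratio = ratio, positive = positive)
  }
  a1 <- score_one(tallies_1p); a19 <- score_one(tallies_19q)
  verdict <- if (!a1$qc$valid || !a19$qc$valid) "not-evaluable"
             else if (a1$positive && a19$positive) "codeleted"
             else "not-codeleted"
  res <- fish_result("1p/19q", verdict,
                     min(a1$fraction, a19$fraction),
                     max(a1$ratio, a19$ratio),
                     list(n_nuclei = min(a1$qc$n_nuclei, a19$qc$n_nuclei),
                          n_zero_green = a1$qc$n_zero_green + a19$qc$n_zero_green,
                          valid = a1$qc$valid && a19$qc$valid))
  res$arms <- list(`1p` = a1, `19q` = a19)
  res
}

#' Score EGFR amplification from FISH tallies
#'
#' Amplified when more than 10\% of nuclei show either a per-nucleus
#' orange/green ratio > 2 or innumerable orange clusters; otherwise gain
#' when the overall orange/green ratio lies in (1, 2]; otherwise normal.
#' Zero-green nuclei are excluded from ratio computations (they still count
#' toward the nucleus total) and tallied in QC.
#'
#' @param tallies tally data.frame for the EGFR/CEP7 probe set.
#' @param config a `gliotyper_config`.
#' @return a `fish_result` with verdict `amplified`/`gain`/`normal`/
#'   `not-evaluable`.
#' @export
score_egfr <- function(tallies, config = default_config()) {
  qc <- fish_qc(tallies, config)
  high <- tallies$cluster |
    (tallies$green > 0 & tallies$orange / pmax(tallies$green, 1) > config$fish$amplification_ratio)
  frac_high <- mean(high)
  ratio <- overall_ratio(tallies)
  verdict <- if (!qc$valid) "not-evaluable"
    else if (frac_high > config$fish$amplification_fraction) "amplified"
    else if (!is.na(ratio) && ratio > 1 && ratio <= config$fish$amplification_ratio) "gain"
    else "normal"
  fish_result("EGFR", verdict, frac_high, ratio, qc)
}

#' Score whole-chromosome 7 gain and chromosome 10 loss from FISH tallies
#'
#' Chromosome 7 gain is positive when >= 30\% of nuclei show 3 orange /
#' 3 green signals (EGFR/CEP7 probes); chromosome 10 loss when >= 30\%
#' show 1 orange / 1 green (PTEN/CEP10 probes).
#'
#' @param tallies_chr7 EGFR/CEP7 tallies.
#' @param tallies_chr10 PTEN/CEP10 tallies.
#' @param config a `gliotyper_config`.
#' @return list of two `fish_result`s: `chr7` (verdict `gain`/`normal`/
#'   `not-evaluable`) and `chr10` (verdict `loss`/`normal`/`not-evaluable`).
#' @export
score_chr7_chr10 <- function(tallies_chr7, tallies_chr10,
                             config = default_config()) {
  qc7 <- fish_qc(tallies_chr7, config)
  frac7 <- mean(tallies_chr7$orange == 3 & tallies_chr7$green == 3)
  v7 <- if (!qc7$valid) "not-evaluable"
        else if (frac7 >= config$fish$chromosome_fraction) "gain" else "normal"
  qc10 <- fish_qc(tallies_chr10, config)
  frac10 <- mean(tallies_chr10$orange == 1 & tallies_chr10$green == 1)
  v10 <- if (!qc10$valid) "not-evaluable"
         else if (frac10 >= config$fish$chromosome_fraction) "loss" else "normal"
  list(chr7 = fish_result("chr7", v7, frac7, overall_ratio(tallies_chr7), qc7),
       chr10 = fish_result("chr10", v10, frac10, overall_ratio(tallies_chr10), qc10))
}

#' Score CDKN2A homozygous deletion from FISH tallies
#'
#' Positive when >= 20\% of nuclei show no orange signal in the presence of
#' at least one reference green signal (0 orange / 1-2 green; CDKN2A/CEP9
#' probes).
#'
#' @param tallies tally data.frame.
#' @param config a `gliotyper_config`.
#' @return a `fish_result` with verdict `homozygous-deletion`/
#'   `no-homozygous-deletion`/`not-evaluable`.
#' @export
score_cdkn2a <- function(tallies, config = default_config()) {
  qc <- fish_qc(tallies, config)
  frac <- mean(tallies$orange == 0 & tallies$green >= 1)
  verdict <- if (!qc$valid) "not-evaluable"
             else if (frac >= config$fish$cdkn2a_fraction) "homozygous-deletion"
             else "no-homozygous-deletion"
  fish_result("CDKN2A", verdict, frac, overall_ratio(tallies), qc)
}
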