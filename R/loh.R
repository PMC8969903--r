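#' Read per-SNP allele depths and compute B-allele frequencies
#'
#' The table is tab-separated with columns `rsid`, `ref_depth`, `alt_depth`
#' (extra columns ignored). BAF is computed as alt/(ref+alt). SNPs with
#' zero total depth get BAF NA and are classified indeterminate downstream;
#' rsIDs absent from the panel manifest are dropped with a message giving
#' the count. The manifest's region tag is attached to each observation.
#'
#' @param path SNP count TSV.
#' @param panel a `panel_design` whose manifest defines the usable SNPs.
#' @return a `snp_observations` data.frame: `rsid`, `region`, `ref_depth`,
#'   `alt_depth`, `depth`, `baf`.
#' @export
read_snp_counts <- function(path, panel) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need_cols(df, c("rsid", "ref_depth", "alt_depth"), "SNP count table")
  snp_observations(df, panel)
}

#' Build SNP observations from an in-memory count table
#'
#' @param df data.frame with `rsid`, `ref_depth`, `alt_depth`.
#' @param panel a `panel_design`.
#' @return a `snp_observations` data.frame (see [read_snp_counts()]).
#' @export
snp_observations <- function(df, panel) {
  known <- df$rsid %in% panel$snps$rsid
  if (any(!known)) {
    message(sum(!known), " SNP(s) not in the panel manifest were dropped")
    df <- df[known, , drop = FALSE]
  }
  depth <- df$ref_depth + df$alt_depth
  out <- data.frame(
    rsid = df$rsid,
    region = panel$snps$region[match(df$rsid, panel$snps$rsid)],
    ref_depth = as.integer(df$ref_depth),
    alt_depth = as.integer(df$alt_depth),
    depth = as.integer(depth),
    baf = ifelse(depth > 0, df$alt_depth / depth, NA_real_),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("snp_observations", "data.frame")
  out
}

#' Classify a SNP's allelic state from its B-allele frequency
#'
#' BAF within the homozygosity windows (0-5\% or 95-100\%, bounds
#' inclusive) is homozygous; within the heterozygosity window (45-60\%,
#' inclusive) balanced; anything else imbalanced — the signature of allelic
#' loss in an impure tumor. Observations with depth below the minimum (or
#' undefined BAF) are indeterminate. Note the heterozygosity window is
#' asymmetric around 0.5 by design of the assay's reported operating
#' windows; it is configurable via `windows$het`.
#'
#' @param baf numeric vector of B-allele frequencies in [0,1] (NA allowed).
#' @param depth integer vector of total depths (recycled if length 1).
#' @param windows list as in `default_config()$baf`.
#' @return character vector in `{"homozygous","balanced","imbalanced",
#'   "indeterminate"}`.
#' @export
classify_snp <- function(baf, depth = Inf, windows = default_config()$baf) {
  depth <- rep_len(depth, length(baf))
  state <- rep("imbalanced", length(baf))
  hom <- (baf >= windows$hom_low[1] & baf <= windows$hom_low[2]) |
         (baf >= windows$hom_high[1] & baf <= windows$hom_high[2])
  het <- baf >= windows$het[1] & baf <= windows$het[2]
  state[het] <- "balanced"
  state[hom] <- "homozygous"
  state[is.na(baf) | depth < windows$min_depth] <- "indeterminate"
  state
}

#' Aggregate SNP states into an arm-level LOH verdict
#'
#' Informative SNPs are the balanced plus imbalanced heterozygous
#' observations (germline-homozygous and indeterminate SNPs carry no
#' tumor-only LOH signal). The arm is called LOH/imbalance when at least
#' `min_informative` SNPs are informative and the imbalanced fraction is at
#' least `min_fraction`; with too few informative SNPs the arm is
#' not-evaluable.
#'
#' @param obs a `snp_observations` data.frame.
#' @param region region tag to evaluate (one of `"1p"`, `"19q"`, `"chr7"`,
#'   `"chr10"`); `NULL` uses all rows of `obs`.
#' @param config a `gliotyper_config`.
#' @return an `arm_loh_call`: `region`, `n_snps`, `n_informative`,
#'   `n_imbalanced`, `imbalanced_fraction` (3 decimals), `verdict` in
#'   `{"LOH","no-LOH","not-evaluable"}`, and the per-SNP `states`.
#' @export
call_arm <- function(obs, region = NULL, config = default_config()) {
  df <- as.data.frame(obs)
  if (!is.null(region)) df <- df[df$region == region, , drop = FALSE]
  states <- if (nrow(df)) classify_snp(df$baf, df$depth, config$baf) else character(0)
  n_bal <- sum(states == "balanced")
  n_imb <- sum(states == "imbalanced")
  n_inf <- n_bal + n_imb
  frac <- if (n_inf > 0) round_half_up(n_imb / n_inf, 3) else NA_real_
  verdict <- if (n_inf < config$arm$min_informative) "not-evaluable"
             else if (frac >= config$arm$min_fraction) "LOH"
             else "no-LOH"
  structure(list(region = region %||% "all", n_snps = nrow(df),
                 n_informative = n_inf, n_imbalanced = n_imb,
                 imbalanced_fraction = frac, verdict = verdict,
                 states = states),
            class = "arm_loh_call")
}

#' @export
print.arm_loh_call <- function(x, ...) {
  cat(sprintf("arm %s: %s (%d/%d informative SNPs imbalanced, fraction %s)\n",
              x$region, x$verdict, x$n_imbalanced, x$n_informative,
              ifelse(is.na(x$imbalanced_fraction), "NA",
                     sprintf("%.3f", x$imbalanced_fraction))))
  invisible(x)
}

#' Combine 1p and 19q arm calls into a co-deletion verdict
#'
#' Co-deletion — the defining marker of oligodendroglioma in IDH-mutant
#' tumors — requires LOH/imbalance on both arms. Single-arm imbalance
#' (e.g. 19q-only loss, seen in a subset of IDH-wildtype glioblastomas) is
#' reported separately via `single_arm`.
#'
#' @param call_1p,call_19q `arm_loh_call` objects for 1p and 19q.
#' @return a `codeletion_call`: `verdict` in `{"codeleted","not-codeleted",
#'   "not-evaluable"}`, `single_arm` (`"1p"`, `"19q"` or `NA`), and the two
#'   arm calls.
#' @export
call_1p19q <- function(call_1p, call_19q) {
  v1 <- call_1p$verdict; v19 <- call_19q$verdict
  if (v1 == "not-evaluable" || v19 == "not-evaluable") {
    verdict <- "not-evaluable"; single <- NA_character_
  } else if (v1 == "LOH" && v19 == "LOH") {
    verdict <- "codeleted"; single <- NA_character_
  } else {
    verdict <- "not-codeleted"
    single <- if (v1 == "LOH") "1p" else if (v19 == "LOH") "19q" else NA_character_
  }
  structure(list(verdict = verdict, single_arm = single,
                 arm_1p = call_1p, arm_19q = call_19q),
            class = "codeletion_call")
}

#' @export
print.codeletion_call <- function(x, ...) {
  cat("1p/19q:", x$verdict,
      if (!is.na(x$single_arm)) sprintf("(%s-only imbalance)", x$single_arm), "\n")
  invisible(x)
}

chrom_direction <- function(arm_call, median_log2, config) {
  if (arm_call$verdict == "not-evaluable") return("not-evaluable")
  if (arm_call$verdict != "LOH") return("none")
  if (is.null(median_log2) || is.na(median_log2)) return("unresolved")
  if (median_log2 > config$direction$gain_log2) "gain"
  else if (median_log2 < config$direction$loss_log2) "loss"
  else "unresolved"
}

#' Call the +7/-10 chromosomal signature
#'
#' Chromosome 7 gain combined with chromosome 10 loss is a molecular
#' hallmark of IDH-wildtype glioblastoma. B-allele-frequency imbalance
#' alone cannot distinguish gain from loss, so the direction is resolved
#' from the chromosome's median coverage log2 ratio: gain requires
#' imbalance with log2 ratio > +0.1, loss requires imbalance with log2
#' ratio < -0.1. Imbalance without directional support is reported as
#' unresolved, never silently assumed.
#'
#' @param call_chr7,call_chr10 `arm_loh_call` objects.
#' @param chr7_log2,chr10_log2 median coverage log2 ratios (NA/NULL when
#'   coverage is unavailable).
#' @param config a `gliotyper_config`.
#' @return a `plus7_minus10_call`: `verdict` in `{"present","absent",
#'   "partial","not-evaluable"}` plus per-chromosome status
#'   (`chr7`, `chr10` in `{"gain","loss","none","unresolved",
#'   "not-evaluable"}`).
#' @export
call_plus7_minus10 <- function(call_chr7, call_chr10,
                               chr7_log2 = NULL, chr10_log2 = NULL,
                               config = default_config()) {
  s7 <- chrom_direction(call_chr7, chr7_log2, config)
  s10 <- chrom_direction(call_chr10, chr10_log2, config)
  gain7 <- s7 == "gain"
  loss10 <- s10 == "loss"    # a coverage "gain" on chromosome 10 is not a loss
  verdict <- if (s7 == "not-evaluable" && s10 == "not-evaluable") "not-evaluable"
    else if (gain7 && loss10) "present"
    else if (s7 == "none" && s10 == "none") "absent"
    else "partial"
  structure(list(verdict = verdict, chr7 = s7, chr10 = s10,
                 chr7_log2 = chr7_log2 %||% NA_real_,
                 chr10_log2 = chr10_log2 %||% NA_real_),
            class = "plus7_minus10_call")
}

#' @export
print.plus7_minus10_call <- function(x, ...) {
  cat(sprintf("+7/-10 signature: %s (chr7 %s, chr10 %s)\n",
              x$verdict, x$chr7, x$chr10))
  invisible(x)
}

#' Export a per-SNP BAF track
#'
#' Tab-separated `rsid`, `region`, `baf`, `state` table matching the
#' BAF-scatter layout used to visualize arm-level LOH.
#'
#' @param obs a `snp_observations` data.frame.
#' @param path output path.
#' @param config a `gliotyper_config`.
#' @return `path`, invisibly.
#' @export
write_baf_track <- function(obs, path, config = default_config()) {
  df <- as.data.frame(obs)
  df$state <- classify_snp(df$baf, df$depth, config$baf)
  utils::write.table(df[, c("rsid", "region", "baf", "state")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
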