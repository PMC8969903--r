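MIN_DISPERSION <- 1e-3  # floor on baseline log2 dispersion (identical normals)

# relative coverage with mean 1 over amplicons
rel_coverage <- function(counts) {
  total <- sum(counts)
  if (total <= 0) abort("zero total coverage: sample fails QC, cannot normalize")
  counts * length(counts) / total
}

#' Build a copy-number baseline from aberration-free samples
#'
#' The baseline holds, per amplicon, the mean relative coverage and the
#' dispersion (standard deviation of log2 relative coverage) across a set
#' of samples known to be free of copy-number alterations — the reference a
#' tumor sample is compared against. A leave-one-out self-check re-calls
#' each baseline sample against a baseline built from the others and flags
#' any with a gene median |log2 ratio| > 0.3, catching a contaminating
#' aberrant sample.
#'
#' @param counts matrix of raw read counts, amplicons x samples, amplicon
#'   rows in genomic order matching `panel$amplicons`.
#' @param panel a `panel_design`.
#' @param config a `gliotyper_config`; `cna$baseline_min_samples` sets the
#'   minimum number of samples (the panel's own reference used ten).
#' @return a `cna_baseline`: `mean_rel`, `log2_sd` (floored), `n_samples`,
#'   `mean_total`, `loo_flagged` (logical per sample).
#' @export
build_baseline <- function(counts, panel, config = default_config()) {
  counts <- as.matrix(counts)
  if (ncol(counts) < config$cna$baseline_min_samples) {
    abort("baseline needs at least ", config$cna$baseline_min_samples,
          " CNA-free samples, got ", ncol(counts))
  }
  if (nrow(counts) != nrow(panel$amplicons)) {
    abort("baseline row count does not match the panel amplicon count")
  }
  rel <- apply(counts, 2, rel_coverage)
  log2rel <- log2(rel + .Machine$double.eps)
  bl <- structure(list(
    mean_rel = rowMeans(rel),
    log2_sd = pmax(apply(log2rel, 1, stats::sd), MIN_DISPERSION),
    n_samples = ncol(counts),
    mean_total = mean(colSums(counts)),
    loo_flagged = rep(FALSE, ncol(counts))
  ), class = "cna_baseline")

  if (ncol(counts) > config$cna$baseline_min_samples) {
    genes <- panel$amplicons$gene
    bl$loo_flagged <- vapply(seq_len(ncol(counts)), function(j) {
      sub <- counts[, -j, drop = FALSE]
      rel_j <- apply(sub, 2, rel_coverage)
      bl_j <- list(mean_rel = rowMeans(rel_j),
                   mean_total = mean(colSums(sub)))
      r <- log2_ratios(counts[, j], bl_j, config)
      gene_med <- tapply(r, genes, stats::median)
      any(abs(gene_med) > 0.3)
    }, logical(1))
  }
  bl
}

log2_ratios <- function(counts, baseline, config) {
  n <- length(counts)
  rel <- counts * n / sum(counts)
  eps_s <- config$cna$epsilon_reads * n / sum(counts)
  eps_b <- config$cna$epsilon_reads * n / baseline$mean_total
  log2((rel + eps_s) / (baseline$mean_rel + eps_b))
}

#' Normalize a sample's amplicon coverage against the baseline
#'
#' Library-size normalizes the raw counts (relative coverage with mean 1
#' across amplicons) and returns per-amplicon
#' log2((sample + eps) / (baseline mean + eps)), where eps corresponds to
#' one read on the normalized scale, so zero-count amplicons stay finite.
#'
#' @param counts raw read-count vector in the panel's amplicon order.
#' @param baseline a `cna_baseline`.
#' @param config a `gliotyper_config`.
#' @return numeric vector of log2 ratios, one per amplicon.
#' @export
normalize_coverage <- function(counts, baseline, config = default_config()) {
  if (length(counts) != length(baseline$mean_rel)) {
    abort("coverage vector length does not match the baseline")
  }
  if (sum(counts) <= 0) abort("zero total coverage: sample fails QC")
  log2_ratios(counts, baseline, config)
}

#' Compute MAPD and the copy-number evaluability gate
#'
#' MAPD is the median over genomically adjacent amplicon pairs of the
#' absolute difference of their log2 ratios — a noise metric insensitive to
#' true copy-number steps (which affect few pairs) but sensitive to
#' amplicon-to-amplicon scatter. A sample is evaluable for copy-number
#' analysis only when MAPD < 0.45 (strict). Note the adjacent-pair form is
#' used, the established definition with a 0.45 operating gate, not the
#' all-pairs reading of the acronym.
#'
#' @param log2r per-amplicon log2 ratios in genomic order.
#' @param config a `gliotyper_config`.
#' @return a `qc_metrics`: `mapd`, `evaluable`.
#' @export
compute_mapd <- function(log2r, config = default_config()) {
  if (length(log2r) < 2) {
    return(structure(list(mapd = NA_real_, evaluable = FALSE),
                     class = "qc_metrics"))
  }
  mapd <- stats::median(abs(diff(log2r)))
  structure(list(mapd = mapd, evaluable = mapd < config$cna$mapd_max),
            class = "qc_metrics")
}

#' @export
print.qc_metrics <- function(x, ...) {
  cat(sprintf("MAPD %.3f -> %s for CNA analysis\n", x$mapd,
              if (x$evaluable) "evaluable" else "NOT evaluable"))
  invisible(x)
}

#' Call a gene-level copy-number alteration
#'
#' The copy-number estimate is CN = 2 * 2^(median log2 ratio) over the
#' gene's amplicons, called as: CN > 4 amplification; 2.5 < CN <= 4 gain;
#' 1.5 <= CN <= 2.5 neutral; 0.5 <= CN < 1.5 hemizygous loss; CN < 0.5
#' homozygous deletion (thresholds chosen to keep NGS and FISH verdicts
#' commensurable: FISH ratio > 2 ~ CN > 4 amplification). The confidence
#' score is -10*log10 of the two-sided Gaussian p-value of the gene's mean
#' log2 ratio against the baseline dispersion over its amplicons; calls
#' with confidence < 30 (p >= 1e-3) are emitted but flagged filtered.
#' Samples failing the MAPD gate return status `not-assessed`.
#'
#' @param log2r per-amplicon log2 ratios for the whole panel.
#' @param baseline a `cna_baseline`.
#' @param gene gene symbol; must exist in the panel.
#' @param panel a `panel_design`.
#' @param qc a `qc_metrics` from [compute_mapd()].
#' @param config a `gliotyper_config`.
#' @return a `gene_cna_call`: `gene`, `status`, `n_amplicons`,
#'   `median_log2`, `cn`, `call`, `confidence`, `filtered`.
#' @export
call_gene_cna <- function(log2r, baseline, gene, panel, qc,
                          config = default_config()) {
  idx <- which(panel$amplicons$gene == gene)
  if (length(idx) == 0) abort("gene '", gene, "' is not on the panel")
  if (!qc$evaluable) {
    return(structure(list(gene = gene, status = STATUS_NOT_ASSESSED,
                          n_amplicons = length(idx), median_log2 = NA_real_,
                          cn = NA_real_, call = NA_character_,
                          confidence = NA_real_, filtered = NA),
                     class = "gene_cna_call"))
  }
  med <- stats::median(log2r[idx])
  cn <- 2 * 2^med
  th <- config$cna
  call <- if (cn > th$cn_amplification) "amplification"
          else if (cn > th$cn_gain) "gain"
          else if (cn >= th$cn_neutral_low) "neutral"
          else if (cn >= th$cn_loss) "hemizygous-loss"
          else "homozygous-deletion"
  se <- sqrt(mean(baseline$log2_sd[idx]^2)) / sqrt(length(idx))
  z <- mean(log2r[idx]) / se
  p <- max(2 * stats::pnorm(-abs(z)), 1e-300)
  confidence <- -10 * log10(p)
  structure(list(gene = gene, status = STATUS_CALLED,
                 n_amplicons = length(idx), median_log2 = med, cn = cn,
                 call = call, confidence = confidence,
                 filtered = confidence < th$min_confidence),
            class = "gene_cna_call")
}

#' @export
print.gene_cna_call <- function(x, ...) {
  if (x$status != STATUS_CALLED) {
    cat(sprintf("%s CNA: %s\n", x$gene, x$status))
  } else {
    cat(sprintf("%s: CN %.2f (%s), median log2 %.3f over %d amplicons, confidence %.1f%s\n",
                x$gene, x$cn, x$call, x$median_log2, x$n_amplicons,
                x$confidence, if (x$filtered) " [filtered]" else ""))
  }
  invisible(x)
}

#' Normalize, QC and call CNAs for a whole sample
#'
#' Convenience wrapper: normalizes coverage, computes MAPD, and calls every
#' requested gene.
#'
#' @param counts raw read-count vector in panel order.
#' @param baseline a `cna_baseline`.
#' @param panel a `panel_design`.
#' @param genes genes to call (default: all panel genes).
#' @param config a `gliotyper_config`.
#' @return a `cna_profile` list: `qc`, `log2_ratios`, `calls` (named list of
#'   `gene_cna_call`).
#' @export
call_cna_profile <- function(counts, baseline, panel,
                             genes = unique(panel$amplicons$gene),
                             config = default_config()) {
  log2r <- normalize_coverage(counts, baseline, config)
  qc <- compute_mapd(log2r, config)
  calls <- lapply(genes, function(g)
    call_gene_cna(log2r, baseline, g, panel, qc, config))
  names(calls) <- genes
  structure(list(qc = qc, log2_ratios = log2r, calls = calls),
            class = "cna_profile")
}

#' @export
print.cna_profile <- function(x, ...) {
  print(x$qc)
  for (call in x$calls) print(call)
  invisible(x)
}

#' Median log2 coverage ratio of amplicons on one chromosome
#'
#' Used to resolve the direction (gain vs loss) of a BAF imbalance.
#'
#' @param log2r per-amplicon log2 ratios.
#' @param panel a `panel_design`.
#' @param chrom chromosome name as in the panel BED.
#' @return median log2 ratio, or NA if no amplicons on that chromosome.
#' @export
chrom_median_log2 <- function(log2r, panel, chrom) {
  idx <- which(panel$amplicons$chrom == chrom)
  if (length(idx) == 0) return(NA_real_)
  stats::median(log2r[idx])
}
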