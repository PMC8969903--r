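#' Reference layout of the assayed MGMT promoter region
#'
#' The assay quantifies methylation at the four CpG cytosines of the
#' 19-mer `CGACGCCCGCAGGTCCTCG` in MGMT exon 1
#' (chr10:131,265,519-131,265,537, GRCh37/hg19). CpG cytosines sit at
#' offsets 1, 4, 8 and 18 of the 19-mer; the five non-CpG cytosines
#' (offsets 6, 7, 10, 15, 16) are used to verify bisulfite conversion.
#'
#' @return list with `sequence`, `start`, `end`, `cpg_positions`,
#'   `noncpg_c_positions` (genomic, 1-based).
#' @export
mgmt_reference <- function() {
  start <- 131265519L
  list(sequence = "CGACGCCCGCAGGTCCTCG",
       start = start, end = start + 18L,
       cpg_positions = start + c(1L, 4L, 8L, 18L) - 1L,
       noncpg_c_positions = start + c(6L, 7L, 10L, 15L, 16L) - 1L)
}

#' Per-site methylated fraction from bisulfite counts
#'
#' After bisulfite conversion, methylated cytosines are read as C
#' (retained) and unmethylated ones as T (converted); the methylated
#' fraction at a site is retained/(retained + converted).
#'
#' @param retained_c reads retaining C.
#' @param converted_t reads converted to T.
#' @return fraction in [0,1]; NA when the site has zero coverage.
#' @export
site_fraction <- function(retained_c, converted_t) {
  total <- retained_c + converted_t
  ifelse(total > 0, retained_c / total, NA_real_)
}

#' Band an average methylation percentage
#'
#' Below 10\% is unmethylated, between 10 and 50\% (inclusive at both
#' bounds) moderately methylated, above 50\% highly methylated.
#'
#' @param average_pct average methylation in percent, in [0, 100].
#' @return `"unmethylated"`, `"moderate"` or `"high"` (vectorized).
#' @export
classify_average <- function(average_pct) {
  stopifnot(all(is.na(average_pct) | (average_pct >= 0 & average_pct <= 100)))
  ifelse(is.na(average_pct), NA_character_,
    ifelse(average_pct < 10, "unmethylated",
      ifelse(average_pct > 50, "high", "moderate")))
}

#' Bisulfite conversion efficiency from non-CpG cytosines
#'
#' Cytosines outside CpG motifs are essentially never methylated, so they
#' should read as T after conversion; the pooled converted fraction
#' estimates conversion efficiency. Samples below the floor fail QC.
#'
#' @param retained_c,converted_t counts at non-CpG cytosine positions
#'   (vectors pooled).
#' @param floor minimum acceptable efficiency (default 0.98).
#' @return list `efficiency` (NA when nothing covered), `qc_pass`
#'   (NA = indeterminate).
#' @export
conversion_efficiency <- function(retained_c, converted_t,
                                  floor = default_config()$methylation$conversion_floor) {
  tot <- sum(retained_c) + sum(converted_t)
  if (tot == 0) return(list(efficiency = NA_real_, qc_pass = NA))
  eff <- sum(converted_t) / tot
  list(efficiency = eff, qc_pass = eff >= floor)
}

#' Call MGMT promoter methylation from per-site bisulfite counts
#'
#' Computes the methylated fraction at each covered CpG site, averages them
#' (unweighted over covered sites), bands the average, and attaches the
#' conversion-efficiency QC. Zero-coverage CpG sites are excluded and
#' flagged; if all four are uncovered the result is `not-assessed`.
#'
#' @param counts data.frame with columns `position`, `context`
#'   (`"CpG"`/`"non-CpG"`), `retained_c`, `converted_t`, as produced by
#'   [read_bisulfite_counts()] or [simulate_bisulfite_counts()].
#' @param config a `gliotyper_config`.
#' @return a `methylation_result`: `status`, `site_fractions` (named by
#'   position), `excluded_sites`, `average_pct`, `band`, `conversion`
#'   (efficiency + qc_pass).
#' @export
call_mgmt <- function(counts, config = default_config()) {
  need_cols(counts, c("position", "context", "retained_c", "converted_t"),
            "bisulfite count table")
  cpg <- counts[counts$context == "CpG", , drop = FALSE]
  non <- counts[counts$context == "non-CpG", , drop = FALSE]
  fr <- site_fraction(cpg$retained_c, cpg$converted_t)
  names(fr) <- cpg$position
  covered <- !is.na(fr)
  conv <- conversion_efficiency(non$retained_c, non$converted_t,
                                config$methylation$conversion_floor)
  if (!any(covered)) {
    return(structure(list(status = STATUS_NOT_ASSESSED,
                          site_fractions = fr[0], excluded_sites = names(fr),
                          average_pct = NA_real_, band = NA_character_,
                          conversion = conv),
                     class = "methylation_result"))
  }
  avg <- mean(fr[covered]) * 100
  status <- if (isFALSE(conv$qc_pass)) STATUS_FAILED_QC else STATUS_CALLED
  structure(list(status = status,
                 site_fractions = fr[covered],
                 excluded_sites = names(fr)[!covered],
                 average_pct = avg,
                 band = classify_average(avg),
                 conversion = conv),
            class = "methylation_result")
}

#' @export
print.methylation_result <- function(x, ...) {
  if (x$status == STATUS_NOT_ASSESSED) {
    cat("MGMT promoter methylation: not assessed (no covered CpG sites)\n")
    return(invisible(x))
  }
  cat(sprintf("MGMT promoter methylation: %.1f%% (%s)%s\n", x$average_pct,
              x$band,
              if (x$status == STATUS_FAILED_QC) " [conversion QC FAILED]" else ""))
  cat(sprintf("  per-site: %s\n",
              paste(sprintf("%s=%.3f", names(x$site_fractions),
                            x$site_fractions), collapse = ", ")))
  if (!is.na(x$conversion$efficiency)) {
    cat(sprintf("  conversion efficiency %.3f\n", x$conversion$efficiency))
  }
  invisible(x)
}

#' Read a bisulfite count table
#'
#' Tab-separated with columns `position`, `context`, `retained_c`,
#' `converted_t`.
#'
#' @param path input TSV.
#' @return the validated data.frame.
#' @export
read_bisulfite_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need_cols(df, c("position", "context", "retained_c", "converted_t"),
            "bisulfite count table")
  df
}

#' Score a CpG site from Sanger chromatogram peak heights
#'
#' Emulates the chromatogram scoring used for orthogonal confirmation: a
#' site is methylated when the cytosine fraction c/(c+t) exceeds 20\%,
#' unmethylated when below; an exact 20\% scores unmethylated (both printed
#' rules are strict, the gap is closed downward). Sites with both peaks
#' zero are excluded.
#'
#' @param c_peak,t_peak non-negative peak heights (vectorized).
#' @return character vector `"methylated"`/`"unmethylated"`, NA for
#'   excluded sites.
#' @export
sanger_site_call <- function(c_peak, t_peak) {
  total <- c_peak + t_peak
  ratio <- ifelse(total > 0, c_peak / total, NA_real_)
  ifelse(is.na(ratio), NA_character_,
         ifelse(ratio > default_config()$methylation$sanger_cutoff,
                "methylated", "unmethylated"))
}

#' Average and band Sanger per-site methylation ratios
#'
#' The per-site cytosine fractions (excluding zero-peak sites) are averaged
#' and banded with [classify_average()], making Sanger and sequencing
#' results directly comparable.
#'
#' @param c_peaks,t_peaks peak heights at the four CpG sites.
#' @return list `site_calls`, `site_ratios`, `average_pct`, `band`.
#' @export
sanger_mgmt <- function(c_peaks, t_peaks) {
  total <- c_peaks + t_peaks
  ratio <- ifelse(total > 0, c_peaks / total, NA_real_)
  avg <- if (all(is.na(ratio))) NA_real_ else mean(ratio, na.rm = TRUE) * 100
  list(site_calls = sanger_site_call(c_peaks, t_peaks),
       site_ratios = ratio,
       average_pct = avg,
       band = classify_average(avg))
}
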