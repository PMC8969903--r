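#' Build a 2x2 agreement table
#'
#' Cross-classifies two assays (conventional testing, CT, vs sequencing,
#' NGS) on a binary marker: `a` positive by both, `b` positive by CT only,
#' `c` positive by NGS only, `d` negative by both.
#'
#' @param a,b,c,d non-negative counts.
#' @return a `contingency_2x2` list with the counts and `n`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("contingency counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0) abort("contingency table is empty")
  structure(list(a = a, b = b, c = c, d = d, n = n),
            class = "contingency_2x2")
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected agreement: observed agreement p_o = (a+d)/N, expected
#' agreement p_e = ((a+b)(a+c) + (c+d)(b+d))/N^2, kappa = (p_o - p_e) /
#' (1 - p_e). Interpretation bands: kappa < 0.4 weak, 0.4 <= kappa < 0.8
#' moderate, kappa >= 0.8 strong. The degenerate case p_e = 1 (both raters
#' constant) yields kappa = 1 when agreement is perfect and is an error
#' otherwise.
#'
#' @param table a `contingency_2x2`.
#' @return a `kappa_result`: `p_o`, `p_e`, `kappa`, `band`.
#' @export
cohens_kappa <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  n <- table$n
  p_o <- (table$a + table$d) / n
  p_e <- ((table$a + table$b) * (table$a + table$c) +
          (table$c + table$d) * (table$b + table$d)) / n^2
  if (1 - p_e == 0) {
    if (p_o == 1) {
      kappa <- 1
    } else {
      abort("kappa undefined: expected agreement is 1 but observed agreement is not")
    }
  } else {
    kappa <- (p_o - p_e) / (1 - p_e)
  }
  band <- if (kappa < 0.4) "weak" else if (kappa < 0.8) "moderate" else "strong"
  structure(list(p_o = p_o, p_e = p_e, kappa = kappa, band = band),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa %.3f (%s agreement; p_o %.3f, p_e %.3f)\n",
              round_half_up(x$kappa, 3), x$band, x$p_o, x$p_e))
  invisible(x)
}

#' Sensitivity and specificity of one assay against the other as reference
#'
#' With NGS as the reference (scoring conventional testing): TP = a,
#' FN = c, TN = d, FP = b. With CT as the reference (scoring NGS): TP = a,
#' FN = b, TN = d, FP = c. Sensitivity = TP/(TP+FN) x 100, specificity =
#' TN/(TN+FP) x 100, reported to 2 decimals (half-up). A zero denominator
#' makes the corresponding value NA ("not computable"), never 0 or 100.
#'
#' @param table a `contingency_2x2`.
#' @param reference `"NGS"` (scores CT) or `"CT"` (scores NGS).
#' @return an `accuracy_result`: `sensitivity`, `specificity` (percent),
#'   `reference`, `scored`.
#' @export
sensitivity_specificity <- function(table, reference = c("NGS", "CT")) {
  stopifnot(inherits(table, "contingency_2x2"))
  reference <- match.arg(reference)
  if (reference == "NGS") {
    tp <- table$a; fn <- table$c; tn <- table$d; fp <- table$b
    scored <- "CT"
  } else {
    tp <- table$a; fn <- table$b; tn <- table$d; fp <- table$c
    scored <- "NGS"
  }
  sens <- if (tp + fn > 0) round_half_up(100 * tp / (tp + fn), 2) else NA_real_
  spec <- if (tn + fp > 0) round_half_up(100 * tn / (tn + fp), 2) else NA_real_
  structure(list(sensitivity = sens, specificity = spec,
                 reference = reference, scored = scored),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("%s scored against %s reference: sensitivity %s%%, specificity %s%%\n",
              x$scored, x$reference,
              ifelse(is.na(x$sensitivity), "NA", format(x$sensitivity)),
              ifelse(is.na(x$specificity), "NA", format(x$specificity))))
  invisible(x)
}

#' Expected-vs-measured allele-frequency regression
#'
#' Ordinary least-squares regression of measured on expected allele
#' frequencies (reference-standard validation); r-squared is the squared
#' Pearson correlation.
#'
#' @param expected,measured paired numeric vectors (>= 3 points; expected
#'   must have positive variance).
#' @return an `af_regression`: `slope`, `intercept`, `r_squared`, `n`.
#' @export
af_regression <- function(expected, measured) {
  if (length(expected) != length(measured)) abort("input lengths differ")
  if (length(expected) < 3) abort("need at least 3 paired allele frequencies")
  if (stats::var(expected) == 0) abort("expected allele frequencies have zero variance")
  fit <- stats::lm(measured ~ expected)
  r2 <- if (stats::var(measured) == 0) 0 else stats::cor(expected, measured)^2
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n = length(expected)),
            class = "af_regression")
}

#' @export
print.af_regression <- function(x, ...) {
  cat(sprintf("AF regression (n=%d): slope %.4f, intercept %.4f, r^2 %.5f\n",
              x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Bundled validation contingency counts
#'
#' The 2x2 counts from the panel's validation against conventional testing
#' (immunohistochemistry, FISH, Sanger), one row per marker:
#' `a` positive by both, `b` positive by conventional testing only, `c`
#' positive by sequencing only, `d` negative by both.
#'
#' @return data.frame with `marker`, `comparator`, `a`, `b`, `c`, `d`.
#' @export
concordance_counts <- function() {
  path <- system.file("extdata", "concordance_counts.tsv", package = "gliotyper")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Recompute all concordance statistics from a counts table
#'
#' For every marker row, computes Cohen's kappa (with band) and sensitivity
#' and specificity in both reference directions.
#'
#' @param counts data.frame as from [concordance_counts()], or a path to a
#'   TSV with columns `marker`, `a`, `b`, `c`, `d`.
#' @return data.frame with one row per marker: `kappa`, `band`,
#'   `sens_ct`, `spec_ct` (CT scored, NGS reference), `sens_ngs`,
#'   `spec_ngs` (NGS scored, CT reference).
#' @export
concordance_table <- function(counts = concordance_counts()) {
  if (is.character(counts)) counts <- utils::read.delim(counts)
  need_cols(counts, c("marker", "a", "b", "c", "d"), "concordance counts")
  do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    tab <- contingency_2x2(counts$a[i], counts$b[i], counts$c[i], counts$d[i])
    k <- cohens_kappa(tab)
    ct <- sensitivity_specificity(tab, "NGS")
    ngs <- sensitivity_specificity(tab, "CT")
    data.frame(marker = counts$marker[i], n = tab$n,
               kappa = k$kappa, band = k$band,
               sens_ct = ct$sensitivity, spec_ct = ct$specificity,
               sens_ngs = ngs$sensitivity, spec_ngs = ngs$specificity,
               stringsAsFactors = FALSE)
  }))
}
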