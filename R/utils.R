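`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (0.5 -> 1), the convention
#' used for the reported concordance percentages, as opposed to base R's
#' round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stop() with a consistent prefix, no call
abort <- function(...) stop(..., call. = FALSE)

# check required columns in a data.frame read from disk
need_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# marker status constants used throughout
STATUS_CALLED <- "called"
STATUS_NOT_ASSESSED <- "not-assessed"
STATUS_FAILED_QC <- "failed-QC"
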