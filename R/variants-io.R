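VARIANT_COLS <- c("chrom", "pos", "ref", "alt", "vaf", "depth", "quality",
                  "pvalue", "gene", "hgvs_c", "hgvs_p", "tier")

#' Build a variant table
#'
#' Normalizes a data.frame of variant calls to the canonical column set and
#' validates ranges. One row per alternate allele; coordinates 1-based.
#' Missing optional annotation columns are added as NA.
#'
#' @param df data.frame with at least `chrom`, `pos`, `ref`, `alt`; optional
#'   `vaf` (fraction in [0,1]), `depth`, `quality` (Phred), `pvalue`,
#'   `gene`, `hgvs_c`, `hgvs_p`, `tier`.
#' @return a `variant_table` data.frame.
#' @export
variant_table <- function(df = data.frame()) {
  if (nrow(df) == 0) {
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(VARIANT_COLS)), VARIANT_COLS))
    df$pos <- integer(0)
    df$vaf <- df$quality <- df$pvalue <- numeric(0)
    df$depth <- integer(0)
    class(df) <- c("variant_table", "data.frame")
    return(df)
  }
  need_cols(df, c("chrom", "pos", "ref", "alt"), "variant table")
  for (col in setdiff(VARIANT_COLS, names(df))) df[[col]] <- NA
  df <- df[, VARIANT_COLS]
  df$pos <- as.integer(df$pos)
  for (col in c("vaf", "quality", "pvalue")) df[[col]] <- as.numeric(df[[col]])
  df$depth <- as.integer(df$depth)
  df$tier <- as.character(df$tier)
  ok_vaf <- is.na(df$vaf) | (df$vaf >= 0 & df$vaf <= 1)
  ok_p <- is.na(df$pvalue) | (df$pvalue >= 0 & df$pvalue <= 1)
  ok_d <- is.na(df$depth) | df$depth >= 0
  ok_q <- is.na(df$quality) | df$quality >= 0
  bad <- which(!(ok_vaf & ok_p & ok_d & ok_q))
  if (length(bad)) {
    abort("variant row(s) out of range (VAF/p in [0,1], depth/quality >= 0): ",
          paste(bad, collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Read variant calls from VCF or a tab-separated table
#'
#' For VCF input, one record is emitted per alternate allele. VAF is taken
#' from a per-sample `AF` FORMAT field when present, otherwise computed from
#' allele depths as alt/(ref+alt) using `AD`; depth from `DP` (FORMAT, then
#' INFO); quality from `QUAL`; the caller p-value from an INFO `PVAL` field
#' when present. Records lacking the fields needed for filtering keep NA
#' there and are excluded (with reason) by [filter_variants()] rather than
#' causing an error.
#'
#' The tab-separated dialect has a header with the columns documented in
#' [variant_table()]; unknown extra columns are ignored.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"vcf"`, or `"tsv"`.
#' @return a `variant_table` data.frame.
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") read_variants_vcf(path) else read_variants_tsv(path)
}

read_variants_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  variant_table(df)
}

read_variants_vcf <- function(path) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) abort("failed to parse VCF '", path,
                                            "': ", conditionMessage(e)))
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(variant_table())
  n_sample <- ncol(vcf@gt) - 1
  ad <- if (n_sample >= 1) vcfR::extract.gt(vcf, "AD") else NULL
  af <- if (n_sample >= 1) suppressWarnings(vcfR::extract.gt(vcf, "AF")) else NULL
  dp_fmt <- if (n_sample >= 1)
    suppressWarnings(vcfR::extract.gt(vcf, "DP", as.numeric = TRUE)) else NULL
  info_field <- function(key) {
    val <- vcfR::extract.info(vcf, key)
    if (is.null(val)) rep(NA_character_, nrow(fix)) else val
  }
  pval <- suppressWarnings(as.numeric(info_field("PVAL")))
  gene <- info_field("GENE")
  hgvs_c <- info_field("HGVSC")
  hgvs_p <- info_field("HGVSP")
  tier <- info_field("TIER")
  dp_info <- suppressWarnings(as.numeric(info_field("DP")))

  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ads <- if (!is.null(ad) && !is.na(ad[i, 1])) {
      suppressWarnings(as.numeric(strsplit(ad[i, 1], ",", fixed = TRUE)[[1]]))
    } else NULL
    depth_i <- if (!is.null(dp_fmt) && !is.na(dp_fmt[i, 1])) dp_fmt[i, 1]
               else if (!is.na(dp_info[i])) dp_info[i]
               else if (!is.null(ads)) sum(ads) else NA_real_
    afs <- if (!is.null(af) && !is.na(af[i, 1])) {
      suppressWarnings(as.numeric(strsplit(af[i, 1], ",", fixed = TRUE)[[1]]))
    } else NULL
    data.frame(
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]), ref = fix$REF[i],
      alt = alts,
      vaf = vapply(seq_along(alts), function(k) {
        if (!is.null(afs) && length(afs) >= k) afs[k]
        else if (!is.null(ads) && length(ads) >= k + 1 && sum(ads) > 0)
          ads[k + 1] / sum(ads)
        else NA_real_
      }, numeric(1)),
      depth = depth_i,
      quality = suppressWarnings(as.numeric(fix$QUAL[i])),
      pvalue = pval[i], gene = gene[i], hgvs_c = hgvs_c[i],
      hgvs_p = hgvs_p[i], tier = tier[i], stringsAsFactors = FALSE)
  })
  variant_table(do.call(rbind, rows))
}

#' Write a variant table to the tab-separated dialect
#'
#' Round-trips with `read_variants(path, format = "tsv")`.
#'
#' @param variants a `variant_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(as.data.frame(variants), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
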