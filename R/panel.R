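REGION_TAGS <- c("1p", "19q", "chr7", "chr10")

#' Construct a panel design
#'
#' A panel design couples the amplicon layout (used for coverage
#' normalization and gene-level copy-number calls) with the SNP manifest
#' (used for B-allele-frequency LOH calling on 1p, 19q, chromosome 7 and
#' chromosome 10). Amplicon coordinates are stored 1-based inclusive.
#'
#' @param amplicons data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive), `pool`, `gene`.
#' @param snps data.frame with columns `rsid`, `chrom`, `pos`, `region`;
#'   `region` must be one of `"1p"`, `"19q"`, `"chr7"`, `"chr10"`.
#' @return a `panel_design` object.
#' @export
panel_design <- function(amplicons, snps) {
  need_cols(amplicons, c("chrom", "start", "end", "pool", "gene"), "amplicon table")
  need_cols(snps, c("rsid", "chrom", "pos", "region"), "SNP manifest")
  if (nrow(amplicons) == 0) abort("panel has no amplicons")
  if (any(amplicons$start > amplicons$end) || any(amplicons$start < 1)) {
    abort("amplicon intervals must be non-empty with start >= 1")
  }
  bad <- !snps$region %in% REGION_TAGS
  if (any(bad)) {
    abort("unknown SNP region tag(s) in manifest row(s): ",
          paste(which(bad), collapse = ", "),
          " (", paste(unique(snps$region[bad]), collapse = ", "), ")")
  }
  if (anyDuplicated(snps$rsid)) abort("duplicated rsIDs in SNP manifest")
  structure(list(amplicons = amplicons, snps = snps), class = "panel_design")
}

#' Read a panel design from a BED file and a SNP manifest
#'
#' The BED file is 0-based half-open (standard BED); coordinates are
#' converted to the internal 1-based inclusive convention on read, so a BED
#' row `chr10 131265518 131265537` becomes the interval
#' 131,265,519-131,265,537. Columns 4 and 5 carry the primer pool and gene.
#' The manifest is tab-separated with columns `rsid`, `chrom`, `pos`,
#' `region`.
#'
#' @param bed_path amplicon BED path (chrom, start, end, pool, gene).
#' @param manifest_path SNP manifest TSV path.
#' @return a `panel_design` object.
#' @export
read_panel <- function(bed_path, manifest_path) {
  bed <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(bed) < 5) abort("amplicon BED needs 5 columns: chrom, start, end, pool, gene")
  amplicons <- data.frame(chrom = as.character(bed[[1]]),
                          start = as.integer(bed[[2]]) + 1L,  # BED -> 1-based
                          end = as.integer(bed[[3]]),
                          pool = as.character(bed[[4]]),
                          gene = as.character(bed[[5]]),
                          stringsAsFactors = FALSE)
  snps <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  need_cols(snps, c("rsid", "chrom", "pos", "region"), "SNP manifest")
  if (nrow(snps) == 0) abort("SNP manifest is empty; LOH calling impossible")
  panel_design(amplicons, snps)
}

#' Write the amplicon layout of a panel back to BED
#'
#' Inverse of the coordinate conversion done by [read_panel()]: internal
#' 1-based inclusive intervals are emitted 0-based half-open.
#'
#' @param panel a `panel_design`.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(panel, path) {
  a <- panel$amplicons
  utils::write.table(
    data.frame(a$chrom, a$start - 1L, a$end, a$pool, a$gene),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-region SNP counts of a panel
#'
#' @param panel a `panel_design`.
#' @return named integer vector over the four region tags.
#' @export
snp_region_counts <- function(panel) {
  counts <- table(factor(panel$snps$region, levels = REGION_TAGS))
  stats::setNames(as.integer(counts), REGION_TAGS)
}

#' @export
print.panel_design <- function(x, ...) {
  rc <- snp_region_counts(x)
  cat("panel design:", nrow(x$amplicons), "amplicons,",
      length(unique(x$amplicons$gene)), "genes,",
      nrow(x$snps), "SNPs\n")
  cat("  SNPs by region:",
      paste(sprintf("%s=%d", names(rc), rc), collapse = ", "), "\n")
  invisible(x)
}
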