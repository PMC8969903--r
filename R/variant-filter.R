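#' Default hotspot rescue list
#'
#' Clinically established hotspots allowed below the standard VAF cutoff
#' (down to the rescue floor, default 2\%): BRAF V600E, IDH1 codon 132,
#' IDH2 codon 172, the two TERT promoter hotspots (c.1-124C>T, c.1-146C>T)
#' and H3-3A K27M. Stored as a tab-separated file so laboratories can edit
#' it; `hgvs_p_pattern`/`hgvs_c_pattern` are regular expressions matched
#' against the variant annotation.
#'
#' @return data.frame with columns `gene`, `hgvs_c_pattern`, `hgvs_p_pattern`.
#' @export
default_hotspots <- function() {
  path <- system.file("extdata", "hotspots.tsv", package = "gliotyper")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

is_hotspot <- function(variants, hotspots) {
  if (nrow(variants) == 0) return(logical(0))
  hit <- rep(FALSE, nrow(variants))
  for (i in seq_len(nrow(hotspots))) {
    g <- !is.na(variants$gene) & variants$gene == hotspots$gene[i]
    pc <- hotspots$hgvs_c_pattern[i]
    pp <- hotspots$hgvs_p_pattern[i]
    m <- rep(FALSE, nrow(variants))
    if (!is.na(pc) && nzchar(pc)) {
      m <- m | (!is.na(variants$hgvs_c) & grepl(pc, variants$hgvs_c))
    }
    if (!is.na(pp) && nzchar(pp)) {
      m <- m | (!is.na(variants$hgvs_p) & grepl(pp, variants$hgvs_p))
    }
    hit <- hit | (g & m)
  }
  hit
}

#' Filter variant calls by VAF, depth, quality and caller p-value
#'
#' A record is retained when VAF >= `min_vaf` (or >= `hotspot_rescue_vaf`
#' for records on the hotspot list), depth > `min_depth`, quality >
#' `min_quality` and p-value < `max_pvalue`. The depth/quality/p-value
#' inequalities are strict, matching the validated operating point
#' (>100, >40, <1e-4); the VAF cutoff is inclusive so boundary calls at
#' exactly 3\% are kept. Records with any required field missing are
#' excluded with reason `missing-<field>` rather than raising an error.
#'
#' @param variants a `variant_table`.
#' @param thresholds list as in `default_config()$variant`.
#' @param hotspots hotspot table as from [default_hotspots()]; `NULL`
#'   disables rescue.
#' @return the retained `variant_table`, row order preserved, with an
#'   `excluded` attribute: a data.frame of removed rows plus a `reason`
#'   column (semicolon-separated machine-readable reasons).
#' @export
filter_variants <- function(variants, thresholds = default_config()$variant,
                            hotspots = default_hotspots()) {
  variants <- variant_table(as.data.frame(variants))
  n <- nrow(variants)
  if (n == 0) {
    attr(variants, "excluded") <- cbind(as.data.frame(variants),
                                        reason = character(0))
    return(variants)
  }
  hot <- if (is.null(hotspots)) rep(FALSE, n) else is_hotspot(variants, hotspots)
  vaf_floor <- ifelse(hot, thresholds$hotspot_rescue_vaf, thresholds$min_vaf)

  reasons <- vector("list", n)
  add <- function(idx, why) for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], why)
  add(is.na(variants$vaf), "missing-vaf")
  add(is.na(variants$depth), "missing-depth")
  add(is.na(variants$quality), "missing-quality")
  add(is.na(variants$pvalue), "missing-pvalue")
  add(!is.na(variants$vaf) & variants$vaf < vaf_floor, "vaf-below-cutoff")
  add(!is.na(variants$depth) & variants$depth <= thresholds$min_depth,
      "depth-not-above-minimum")
  add(!is.na(variants$quality) & variants$quality <= thresholds$min_quality,
      "quality-not-above-minimum")
  add(!is.na(variants$pvalue) & variants$pvalue >= thresholds$max_pvalue,
      "pvalue-not-below-maximum")

  keep <- vapply(reasons, is.null, logical(1))
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_table", "data.frame")
  excluded <- as.data.frame(variants[!keep, , drop = FALSE])
  excluded$reason <- vapply(reasons[!keep], paste, character(1), collapse = ";")
  rownames(excluded) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Annotate variants with pathogenicity tiers
#'
#' Looks each variant up in a tier table (curated pathogenicity ranks, e.g.
#' from a mutation census) by genomic key `chrom:pos:ref:alt`, falling back
#' to `gene` + `hgvs_c`. Tiers 1-3 are considered pathogenic by default;
#' variants without an annotation are not pathogenic and flagged
#' `no-annotation`.
#'
#' @param variants a `variant_table`.
#' @param tier_table data.frame with `tier` plus either
#'   `chrom`,`pos`,`ref`,`alt` or `gene`,`hgvs_c`.
#' @param pathogenic_tiers character vector of tier labels counted as
#'   pathogenic.
#' @return `variants` with columns `tier`, `pathogenic` (logical) and
#'   `annotation_status` (`"annotated"`/`"no-annotation"`).
#' @export
classify_pathogenicity <- function(variants, tier_table,
                                   pathogenic_tiers = default_config()$variant$pathogenic_tiers) {
  variants <- variant_table(as.data.frame(variants))
  by_coord <- all(c("chrom", "pos", "ref", "alt") %in% names(tier_table))
  by_hgvs <- all(c("gene", "hgvs_c") %in% names(tier_table))
  if (!"tier" %in% names(tier_table) || !(by_coord || by_hgvs)) {
    abort("tier table needs a 'tier' column plus chrom/pos/ref/alt or gene/hgvs_c keys")
  }
  tier <- rep(NA_character_, nrow(variants))
  if (nrow(variants)) {
    if (by_coord) {
      key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
      tkey <- paste(tier_table$chrom, tier_table$pos, tier_table$ref, tier_table$alt)
      m <- match(key, tkey)
      tier[!is.na(m)] <- as.character(tier_table$tier[m[!is.na(m)]])
    }
    if (by_hgvs) {
      need <- is.na(tier)
      key <- paste(variants$gene, variants$hgvs_c)
      tkey <- paste(tier_table$gene, tier_table$hgvs_c)
      m <- match(key, tkey)
      fill <- need & !is.na(m)
      tier[fill] <- as.character(tier_table$tier[m[fill]])
    }
  }
  variants$tier <- tier
  variants$pathogenic <- !is.na(tier) & tier %in% pathogenic_tiers
  variants$annotation_status <- ifelse(is.na(tier), "no-annotation", "annotated")
  variants
}

#' Call TERT promoter status
#'
#' Maps the two recurrent promoter hotspots to their common names:
#' c.1-124C>T is C228T and c.1-146C>T is C250T (positions relative to the
#' TERT translation start vs. genomic coordinates). Any other promoter
#' variant surviving filters is labelled `other`; none means wild-type.
#'
#' @param variants filtered `variant_table` restricted to the TERT promoter
#'   amplicon (rows with `gene != "TERT"` are ignored).
#' @return a `tert_status` list: `status` (`mutant`/`wild-type`),
#'   `hotspot` (`C228T`/`C250T`/`other`/`none`), `hgvs_c`.
#' @export
call_tert_promoter <- function(variants) {
  v <- as.data.frame(variants)
  v <- v[!is.na(v$gene) & v$gene == "TERT" &
           !is.na(v$hgvs_c) & grepl("^c\\.1-", v$hgvs_c), , drop = FALSE]
  if (nrow(v) == 0) {
    res <- list(status = "wild-type", hotspot = "none", hgvs_c = NA_character_)
  } else {
    labels <- ifelse(v$hgvs_c == "c.1-124C>T", "C228T",
              ifelse(v$hgvs_c == "c.1-146C>T", "C250T", "other"))
    # prefer a named hotspot if present among several promoter calls
    pick <- order(match(labels, c("C228T", "C250T", "other")))[1]
    res <- list(status = "mutant", hotspot = labels[pick], hgvs_c = v$hgvs_c[pick])
  }
  structure(res, class = "tert_status")
}

#' @export
print.tert_status <- function(x, ...) {
  cat("TERT promoter:", x$status,
      if (x$status == "mutant") paste0("(", x$hotspot, ", ", x$hgvs_c, ")"), "\n")
  invisible(x)
}

is_truncating <- function(hgvs_p) {
  !is.na(hgvs_p) & grepl("Ter|fs|\\*$", hgvs_p)
}

#' Derive per-gene marker states from filtered, tier-annotated variants
#'
#' Summarizes the diagnostic genes into the states the integrated
#' classifier consumes:
#' * IDH (IDH1/IDH2): `mutant-canonical-R132H`, `mutant-noncanonical`
#'   (other codon-132 / IDH2 codon-172 or pathogenic IDH variants), or
#'   `wild-type`;
#' * ATRX: `truncating` (nonsense/frameshift), `pathogenic-missense`
#'   (tier-annotated pathogenic missense) or `wild-type` — unannotated
#'   missense variants are not called loss events;
#' * H3-3A: `K27M` or `wild-type`;
#' * TP53: mutation class `missense`, `nonsense-truncating`, or `none`;
#' * BRAF: `V600E`, `other-pathogenic`, or `wild-type`.
#'
#' When a gene carries variants supporting different states, all supporting
#' variants are kept and the most severe state is reported.
#'
#' @param variants a filtered `variant_table` with `pathogenic` column (see
#'   [classify_pathogenicity()]); if absent, tier membership is used.
#' @return a `marker_states` named list; each element has `gene`, `state`
#'   and `variants` (the supporting rows).
#' @export
derive_marker_states <- function(variants) {
  v <- as.data.frame(variants)
  if (!"pathogenic" %in% names(v)) {
    v$pathogenic <- !is.na(v$tier) &
      v$tier %in% default_config()$variant$pathogenic_tiers
  }
  gene_rows <- function(genes) v[!is.na(v$gene) & v$gene %in% genes, , drop = FALSE]

  # IDH: severity mutant-canonical-R132H > mutant-noncanonical > wild-type
  idh <- gene_rows(c("IDH1", "IDH2"))
  idh <- idh[idh$pathogenic |
               (!is.na(idh$hgvs_p) & grepl("R132|Arg132|R172|Arg172", idh$hgvs_p)), ,
             drop = FALSE]
  idh_state <- if (nrow(idh) == 0) "wild-type"
    else if (any(grepl("R132H|Arg132His", idh$hgvs_p))) "mutant-canonical-R132H"
    else "mutant-noncanonical"

  atrx <- gene_rows("ATRX")
  atrx_trunc <- is_truncating(atrx$hgvs_p)
  atrx <- atrx[atrx_trunc | atrx$pathogenic, , drop = FALSE]
  atrx_state <- if (nrow(atrx) == 0) "wild-type"
    else if (any(is_truncating(atrx$hgvs_p))) "truncating"
    else "pathogenic-missense"

  h3 <- gene_rows(c("H3-3A", "H3F3A"))
  h3 <- h3[!is.na(h3$hgvs_p) & grepl("K27M|Lys27Met", h3$hgvs_p), , drop = FALSE]
  h3_state <- if (nrow(h3)) "K27M" else "wild-type"

  tp53 <- gene_rows("TP53")
  tp53 <- tp53[tp53$pathogenic | is_truncating(tp53$hgvs_p), , drop = FALSE]
  tp53_state <- if (nrow(tp53) == 0) "none"
    else if (any(is_truncating(tp53$hgvs_p))) "nonsense-truncating"
    else "missense"

  braf <- gene_rows("BRAF")
  braf <- braf[braf$pathogenic |
                 (!is.na(braf$hgvs_p) & grepl("V600E|Val600Glu", braf$hgvs_p)), ,
               drop = FALSE]
  braf_state <- if (nrow(braf) == 0) "wild-type"
    else if (any(grepl("V600E|Val600Glu", braf$hgvs_p))) "V600E"
    else "other-pathogenic"

  mk <- function(gene, state, rows) list(gene = gene, state = state, variants = rows)
  structure(list(
    IDH = mk("IDH1/IDH2", idh_state, idh),
    ATRX = mk("ATRX", atrx_state, atrx),
    H3_3A = mk("H3-3A", h3_state, h3),
    TP53 = mk("TP53", tp53_state, tp53),
    BRAF = mk("BRAF", braf_state, braf)
  ), class = "marker_states")
}

#' @export
print.marker_states <- function(x, ...) {
  for (m in x) {
    cat(sprintf("  %-10s %s (%d supporting variant%s)\n", m$gene, m$state,
                nrow(m$variants), if (nrow(m$variants) == 1) "" else "s"))
  }
  invisible(x)
}
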