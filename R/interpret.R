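#' Interpret one sample end to end
#'
#' Runs every assay for which input is provided and combines the results
#' into a molecular profile, an integrated diagnosis and an actionability
#' report. Assays without input are reported `not-assessed`, never
#' defaulted.
#'
#' @param panel a `panel_design`.
#' @param variants a `variant_table` of raw calls, or NULL.
#' @param tier_table pathogenicity tier table (see
#'   [classify_pathogenicity()]), or NULL to skip annotation.
#' @param snp_counts a `snp_observations` table (or raw data.frame with
#'   `rsid`, `ref_depth`, `alt_depth`), or NULL.
#' @param coverage raw amplicon read-count vector in panel order, or NULL.
#' @param baseline a `cna_baseline` (required with `coverage`).
#' @param bisulfite bisulfite count data.frame (see [call_mgmt()]), or NULL.
#' @param sample_id identifier.
#' @param config a `gliotyper_config`.
#' @return a `glioma_report`: `profile`, `diagnosis`, `actionability`, and
#'   the per-assay detail objects (`marker_states`, `tert`, `arms`,
#'   `codeletion`, `signature`, `cna`, `mgmt`, `filtered_variants`).
#' @export
interpret_sample <- function(panel, variants = NULL, tier_table = NULL,
                             snp_counts = NULL, coverage = NULL,
                             baseline = NULL, bisulfite = NULL,
                             sample_id = "sample", config = default_config()) {
  details <- list()
  prof_args <- list(sample_id = sample_id)
  alterations <- empty_alterations()
  mapped_genes <- unique(trial_mapping()$gene)

  if (!is.null(variants)) {
    filtered <- filter_variants(variants, config$variant)
    if (!is.null(tier_table)) {
      filtered <- classify_pathogenicity(filtered, tier_table,
                                         config$variant$pathogenic_tiers)
    } else {
      filtered$pathogenic <- !is.na(filtered$tier) &
        filtered$tier %in% config$variant$pathogenic_tiers
    }
    states <- derive_marker_states(filtered)
    tert <- call_tert_promoter(filtered)
    details$filtered_variants <- filtered
    details$marker_states <- states
    details$tert <- tert
    prof_args$idh <- states$IDH$state
    prof_args$atrx <- states$ATRX$state
    prof_args$h3 <- states$H3_3A$state
    prof_args$tp53 <- states$TP53$state
    prof_args$tert <- tert$status
    vmut <- filtered[filtered$pathogenic & !is.na(filtered$gene) &
                       filtered$gene %in% mapped_genes, , drop = FALSE]
    if (nrow(vmut)) {
      alterations <- rbind(alterations, data.frame(
        gene = vmut$gene,
        alteration = ifelse(is.na(vmut$hgvs_p), vmut$hgvs_c, vmut$hgvs_p),
        class = "mutation", vaf = vmut$vaf, cn = NA_real_,
        pathogenic = TRUE, hotspot = is_hotspot(vmut, default_hotspots()),
        stringsAsFactors = FALSE))
    }
  }

  log2r <- NULL
  if (!is.null(coverage)) {
    if (is.null(baseline)) abort("coverage given without a baseline")
    cna <- call_cna_profile(coverage, baseline, panel,
                            genes = setdiff(unique(panel$amplicons$gene),
                                            "FILLER"),
                            config = config)
    details$cna <- cna
    log2r <- cna$log2_ratios
    get_call <- function(g) {
      if (!g %in% names(cna$calls)) return(not_assessed())
      cc <- cna$calls[[g]]
      if (cc$status != STATUS_CALLED) marker(NA_character_, cc$status)
      else marker(cc$call)
    }
    prof_args$egfr <- get_call("EGFR")
    prof_args$cdkn2a <- get_call("CDKN2A")
    for (g in intersect(names(cna$calls), mapped_genes)) {
      cc <- cna$calls[[g]]
      if (cc$status == STATUS_CALLED && !cc$filtered &&
          cc$call %in% c("amplification", "homozygous-deletion")) {
        cls <- if (cc$call == "amplification") "amplification" else "deletion"
        alterations <- rbind(alterations, data.frame(
          gene = g, alteration = cls, class = cls, vaf = NA_real_,
          cn = cc$cn, pathogenic = NA, hotspot = NA, stringsAsFactors = FALSE))
      }
    }
  }

  if (!is.null(snp_counts)) {
    obs <- if (inherits(snp_counts, "snp_observations")) snp_counts
           else snp_observations(snp_counts, panel)
    arms <- lapply(stats::setNames(REGION_TAGS, REGION_TAGS),
                   function(r) call_arm(obs, r, config))
    codel <- call_1p19q(arms[["1p"]], arms[["19q"]])
    sig <- call_plus7_minus10(
      arms[["chr7"]], arms[["chr10"]],
      if (!is.null(log2r)) chrom_median_log2(log2r, panel, "chr7"),
      if (!is.null(log2r)) chrom_median_log2(log2r, panel, "chr10"),
      config)
    details$arms <- arms
    details$codeletion <- codel
    details$signature <- sig
    prof_args$codeletion <- if (codel$verdict == "not-evaluable")
      marker(NA_character_, STATUS_FAILED_QC) else marker(codel$verdict)
    prof_args$plus7_minus10 <- if (sig$verdict == "not-evaluable")
      marker(NA_character_, STATUS_FAILED_QC) else marker(sig$verdict)
  }

  if (!is.null(bisulfite)) {
    mg <- call_mgmt(bisulfite, config)
    details$mgmt <- mg
    prof_args$mgmt <- if (mg$status == STATUS_CALLED) marker(mg$band)
                      else marker(NA_character_, mg$status)
  }

  prof_args$alterations <- alterations
  profile <- do.call(molecular_profile, prof_args)
  structure(c(list(profile = profile,
                   diagnosis = classify_profile(profile),
                   actionability = actionable_report(profile)),
              details),
            class = "glioma_report")
}

#' @export
print.glioma_report <- function(x, ...) {
  cat("== sample", x$profile$sample_id, "==\n")
  print(x$diagnosis)
  print(x$actionability)
  invisible(x)
}

#' @export
summary.glioma_report <- function(object, ...) {
  x <- object
  cat("== sample", x$profile$sample_id, "==\n")
  p <- x$profile
  for (mk in c("idh", "codeletion", "atrx", "tert", "egfr", "plus7_minus10",
               "cdkn2a", "h3", "tp53", "mgmt")) {
    m <- p[[mk]]
    cat(sprintf("  %-14s %s\n", mk,
                if (m$status == STATUS_CALLED) m$state else m$status))
  }
  print(x$diagnosis)
  print(x$actionability)
  invisible(x)
}
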