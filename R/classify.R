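#' Marker state with an explicit assessment status
#'
#' @param state marker-specific state string (NA when not called).
#' @param status `"called"`, `"not-assessed"` or `"failed-QC"`.
#' @return a list with `state` and `status`, accepted by
#'   [molecular_profile()].
#' @export
marker <- function(state, status = STATUS_CALLED) {
  list(state = state, status = status)
}

not_assessed <- function() marker(NA_character_, STATUS_NOT_ASSESSED)

#' Assemble a molecular profile
#'
#' Collects the per-assay marker states into the structure the integrated
#' classifier consumes. Every marker carries a status
#' (`called` / `not-assessed` / `failed-QC`); omitted markers default to
#' not-assessed, so absence is explicit, never a silent negative.
#'
#' @param idh IDH state: `mutant-canonical-R132H`, `mutant-noncanonical`,
#'   `wild-type`.
#' @param codeletion 1p/19q verdict: `codeleted`, `not-codeleted`,
#'   `not-evaluable`.
#' @param atrx `truncating`, `pathogenic-missense`, `wild-type`.
#' @param tert `mutant`, `wild-type`.
#' @param egfr EGFR CNA call (`amplification`, `gain`, `neutral`, ...).
#' @param plus7_minus10 `present`, `absent`, `partial`, `not-evaluable`.
#' @param cdkn2a CDKN2A/B call (`homozygous-deletion`, `hemizygous-loss`,
#'   `neutral`, ...).
#' @param h3 `K27M`, `wild-type`.
#' @param tp53 `missense`, `nonsense-truncating`, `none`.
#' @param mgmt methylation band (`unmethylated`, `moderate`, `high`).
#' @param alterations data.frame of per-gene actionable alterations with
#'   columns `gene`, `alteration`, `class` (`mutation`/`amplification`/
#'   `deletion`), `vaf`, `cn`, `pathogenic` (logical), `hotspot` (logical).
#'   Each marker argument may be a bare state string (status `called`) or a
#'   `marker(state, status)` list.
#' @param sample_id optional identifier.
#' @return a `molecular_profile`.
#' @export
molecular_profile <- function(idh = not_assessed(), codeletion = not_assessed(),
                              atrx = not_assessed(), tert = not_assessed(),
                              egfr = not_assessed(),
                              plus7_minus10 = not_assessed(),
                              cdkn2a = not_assessed(), h3 = not_assessed(),
                              tp53 = not_assessed(), mgmt = not_assessed(),
                              alterations = empty_alterations(),
                              sample_id = NA_character_) {
  as_marker <- function(x) {
    if (is.character(x)) marker(x)
    else if (is.list(x) && all(c("state", "status") %in% names(x))) x
    else abort("markers must be state strings or marker(state, status) lists")
  }
  structure(list(sample_id = sample_id,
                 idh = as_marker(idh), codeletion = as_marker(codeletion),
                 atrx = as_marker(atrx), tert = as_marker(tert),
                 egfr = as_marker(egfr),
                 plus7_minus10 = as_marker(plus7_minus10),
                 cdkn2a = as_marker(cdkn2a), h3 = as_marker(h3),
                 tp53 = as_marker(tp53), mgmt = as_marker(mgmt),
                 alterations = alterations),
            class = "molecular_profile")
}

#' @rdname molecular_profile
#' @export
empty_alterations <- function() {
  data.frame(gene = character(0), alteration = character(0),
              class = character(0), vaf = numeric(0), cn = numeric(0),
              pathogenic = logical(0), hotspot = logical(0),
              stringsAsFactors = FALSE)
}

is_state <- function(m, states) m$status == STATUS_CALLED && m$state %in% states

DIAGNOSIS_LABELS <- c(
  midline = "diffuse midline glioma, H3 K27-altered",
  oligo = "oligodendroglioma, IDH-mutant and 1p/19q-codeleted",
  astro = "astrocytoma, IDH-mutant",
  astro4 = "astrocytoma, IDH-mutant, CDKN2A/B homozygous deletion (grade 4 marker)",
  gbm = "glioblastoma, IDH-wildtype",
  nos = "not-classifiable-by-molecular-criteria")

#' Integrated molecular classification of a glioma profile
#'
#' Applies the WHO-CNS5-style decision rules in a fixed precedence order:
#' 1. H3-3A K27M: diffuse midline glioma, H3 K27-altered;
#' 2. IDH mutant with 1p/19q co-deletion: oligodendroglioma (ATRX loss
#'    co-occurring raises a caveat, as it argues for astrocytoma);
#' 3. IDH mutant without co-deletion: astrocytoma, IDH-mutant — with the
#'    CDKN2A/B homozygous-deletion grade-4 marker when present; ATRX loss
#'    is recorded as supporting evidence;
#' 4. IDH wild-type with TERT promoter mutation, EGFR amplification, or the
#'    +7/-10 signature: glioblastoma, IDH-wildtype;
#' 5. otherwise not classifiable by molecular criteria; the caveats list
#'    the missing or negative markers.
#' Atypical combinations (e.g. 1p/19q co-deletion with IDH wild-type, which
#' does occur in rare glioblastomas) produce caveats, not errors. The
#' classification is a pure function of the profile.
#'
#' @param profile a `molecular_profile`.
#' @return an `integrated_diagnosis`: `label`, `rule_trace` (rules fired,
#'   in order), `caveats`.
#' @export
classify_profile <- function(profile) {
  p <- profile
  trace <- character(0)
  caveats <- character(0)
  idh_mut <- is_state(p$idh, c("mutant-canonical-R132H", "mutant-noncanonical"))
  codel <- is_state(p$codeletion, "codeleted")
  atrx_loss <- is_state(p$atrx, c("truncating", "pathogenic-missense"))

  if (is_state(p$h3, "K27M")) {
    label <- DIAGNOSIS_LABELS[["midline"]]
    trace <- "rule-1: H3-3A K27M"
  } else if (idh_mut && codel) {
    label <- DIAGNOSIS_LABELS[["oligo"]]
    trace <- "rule-2: IDH mutant + 1p/19q codeleted"
    if (atrx_loss) {
      caveats <- c(caveats,
        "ATRX loss co-occurring with 1p/19q co-deletion is atypical for oligodendroglioma")
    }
  } else if (idh_mut) {
    if (is_state(p$cdkn2a, "homozygous-deletion")) {
      label <- DIAGNOSIS_LABELS[["astro4"]]
      trace <- c("rule-3: IDH mutant, not codeleted",
                 "rule-3a: CDKN2A/B homozygous deletion (grade 4 marker)")
    } else {
      label <- DIAGNOSIS_LABELS[["astro"]]
      trace <- "rule-3: IDH mutant, not codeleted"
    }
    if (atrx_loss) trace <- c(trace, "supporting: ATRX loss")
  } else if (is_state(p$idh, "wild-type") &&
             (is_state(p$tert, "mutant") ||
              is_state(p$egfr, "amplification") ||
              is_state(p$plus7_minus10, "present"))) {
    label <- DIAGNOSIS_LABELS[["gbm"]]
    fired <- c(
      if (is_state(p$tert, "mutant")) "TERT promoter mutant",
      if (is_state(p$egfr, "amplification")) "EGFR amplified",
      if (is_state(p$plus7_minus10, "present")) "+7/-10 signature")
    trace <- paste0("rule-4: IDH wild-type + ", paste(fired, collapse = " + "))
    if (codel) {
      caveats <- c(caveats,
        "atypical combination: 1p/19q co-deletion with IDH wild-type")
    }
  } else {
    label <- DIAGNOSIS_LABELS[["nos"]]
    missing <- names(p)[vapply(p, function(m)
      is.list(m) && identical(m$status, STATUS_NOT_ASSESSED), logical(1))]
    caveats <- c(caveats, paste0(
      "no molecular rule fired; markers not assessed: ",
      if (length(missing)) paste(missing, collapse = ", ") else "none",
      "; assessed markers negative or non-diagnostic"))
    if (codel) {
      caveats <- c(caveats,
        "atypical combination: 1p/19q co-deletion without IDH mutation")
    }
  }
  structure(list(label = label, rule_trace = trace, caveats = caveats),
            class = "integrated_diagnosis")
}

#' @export
print.integrated_diagnosis <- function(x, ...) {
  cat("integrated diagnosis:", x$label, "\n")
  for (r in x$rule_trace) cat("  -", r, "\n")
  for (cv in x$caveats) cat("  caveat:", cv, "\n")
  invisible(x)
}

#' Load the bundled gene-to-trial mapping
#'
#' Clinical-trial options for targeted treatment of malignant glioma,
#' keyed by altered gene. Combined entries (`CDK4/CDK6`) are expanded to
#' one row per gene.
#'
#' @return data.frame with `gene`, `agent`, `combination`, `trial`.
#' @export
trial_mapping <- function() {
  path <- system.file("extdata", "glioma_trials.tsv", package = "gliotyper")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  split_rows <- lapply(seq_len(nrow(df)), function(i) {
    genes <- strsplit(df$gene[i], "/", fixed = TRUE)[[1]]
    data.frame(gene = genes, agent = df$agent[i],
               combination = df$combination[i], trial = df$trial[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, split_rows)
}

ACTIONABLE_VAF_MIN <- 0.15

#' Match a profile's alterations to clinical trials
#'
#' An alteration qualifies when it is a copy-number alteration in a mapped
#' gene, or a pathogenic/likely-pathogenic mutation: tier-annotated
#' pathogenic, or a hotspot alteration with VAF >= 15\%. Sub-threshold
#' alterations are listed but do not set the actionable flag. Genes absent
#' from the mapping are ignored.
#'
#' @param profile a `molecular_profile` (its `alterations` table is used).
#' @param mapping trial mapping as from [trial_mapping()].
#' @return an `actionability_report`: `rows` (gene, alteration, agent,
#'   combination, trial), `actionable` flag, `n_qualifying`.
#' @export
actionable_report <- function(profile, mapping = trial_mapping()) {
  alt <- profile$alterations
  alt <- alt[alt$gene %in% mapping$gene, , drop = FALSE]
  qualifies <- alt$class %in% c("amplification", "deletion") |
    (alt$pathogenic & !is.na(alt$vaf)) |
    (alt$hotspot & !is.na(alt$vaf) & alt$vaf >= ACTIONABLE_VAF_MIN)
  qual <- alt[qualifies, , drop = FALSE]
  rows <- if (nrow(qual)) {
    merged <- merge(qual[, c("gene", "alteration", "class")], mapping,
                    by = "gene")
    merged[order(merged$gene, merged$trial), , drop = FALSE]
  } else {
    data.frame(gene = character(0), alteration = character(0),
               class = character(0), agent = character(0),
               combination = character(0), trial = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(rows) <- NULL
  structure(list(rows = rows, actionable = nrow(qual) > 0,
                 n_qualifying = nrow(qual)),
            class = "actionability_report")
}

#' @export
print.actionability_report <- function(x, ...) {
  cat("actionable:", x$actionable,
      sprintf("(%d qualifying alteration%s, %d trial match%s)\n",
              x$n_qualifying, if (x$n_qualifying == 1) "" else "s",
              nrow(x$rows), if (nrow(x$rows) == 1) "" else "es"))
  if (nrow(x$rows)) print(x$rows)
  invisible(x)
}

#' Summarize a cohort of classified samples
#'
#' Per-marker positivity counts with their denominators (samples actually
#' assessed for that marker), the actionability rate with numerator and
#' denominator, the diagnosis distribution, and a gene x sample alteration
#' matrix in the style of a cohort landscape figure.
#'
#' @param samples list; each element a list with components `profile`
#'   (`molecular_profile`), `diagnosis` (`integrated_diagnosis`) and
#'   `report` (`actionability_report`).
#' @return a `cohort_summary`: `n`, `marker_counts` (data.frame marker /
#'   positive / assessed), `actionability` (list rate, numerator,
#'   denominator), `diagnoses` (table), `alteration_matrix` (gene x sample
#'   character matrix of alteration classes).
#' @export
cohort_summary <- function(samples) {
  if (length(samples) == 0) {
    return(structure(list(n = 0L, marker_counts = NULL,
                          actionability = list(rate = NA_real_, numerator = 0L,
                                               denominator = 0L),
                          diagnoses = table(character(0)),
                          alteration_matrix = matrix(character(0), 0, 0)),
                     class = "cohort_summary"))
  }
  profiles <- lapply(samples, `[[`, "profile")
  positive_states <- list(
    idh = c("mutant-canonical-R132H", "mutant-noncanonical"),
    codeletion = "codeleted",
    atrx = c("truncating", "pathogenic-missense"),
    tert = "mutant",
    egfr = "amplification",
    plus7_minus10 = "present",
    cdkn2a = "homozygous-deletion",
    h3 = "K27M",
    tp53 = c("missense", "nonsense-truncating"),
    mgmt = c("moderate", "high"))
  marker_counts <- do.call(rbind, lapply(names(positive_states), function(mk) {
    assessed <- vapply(profiles, function(p)
      p[[mk]]$status == STATUS_CALLED, logical(1))
    positive <- vapply(profiles, function(p)
      is_state(p[[mk]], positive_states[[mk]]), logical(1))
    data.frame(marker = mk, positive = sum(positive), assessed = sum(assessed),
               stringsAsFactors = FALSE)
  }))
  actionable <- vapply(samples, function(s) s$report$actionable, logical(1))
  diagnoses <- table(vapply(samples, function(s) s$diagnosis$label, character(1)))

  genes <- sort(unique(unlist(lapply(profiles, function(p) p$alterations$gene))))
  ids <- vapply(seq_along(profiles), function(i)
    profiles[[i]]$sample_id %||% NA_character_, character(1))
  ids[is.na(ids)] <- paste0("sample", which(is.na(ids)))
  mat <- matrix("", nrow = length(genes), ncol = length(profiles),
                dimnames = list(genes, ids))
  for (i in seq_along(profiles)) {
    a <- profiles[[i]]$alterations
    for (j in seq_len(nrow(a))) {
      cur <- mat[a$gene[j], i]
      mat[a$gene[j], i] <- if (nzchar(cur)) paste(cur, a$class[j], sep = ";")
                           else a$class[j]
    }
  }
  structure(list(n = length(samples), marker_counts = marker_counts,
                 actionability = list(rate = mean(actionable),
                                      numerator = sum(actionable),
                                      denominator = length(actionable)),
                 diagnoses = diagnoses, alteration_matrix = mat),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("cohort of", x$n, "samples\n")
  if (x$n == 0) return(invisible(x))
  cat(sprintf("actionability: %d/%d (%.1f%%)\n",
              x$actionability$numerator, x$actionability$denominator,
              100 * x$actionability$rate))
  cat("diagnoses:\n")
  for (d in names(x$diagnoses)) cat(sprintf("  %2d  %s\n", x$diagnoses[[d]], d))
  cat("marker positivity (positive/assessed):\n")
  with(x$marker_counts,
       cat(sprintf("  %-14s %d/%d\n", marker, positive, assessed), sep = ""))
  invisible(x)
}

#' Export the cohort alteration matrix as a gene x sample table
#'
#' @param summary a `cohort_summary`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_alteration_matrix <- function(summary, path) {
  utils::write.table(summary$alteration_matrix, path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}
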