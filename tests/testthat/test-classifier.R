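exemplar_profiles <- function() {
  list(
    astro_r132s = molecular_profile(idh = "mutant-noncanonical",
                                    atrx = "truncating",
                                    codeletion = "not-codeleted"),
    oligo = molecular_profile(idh = "mutant-canonical-R132H",
                              codeletion = "codeleted"),
    midline = molecular_profile(h3 = "K27M"),
    gbm = molecular_profile(idh = "wild-type", tert = "mutant",
                            plus7_minus10 = "present"))
}

test_that("the four exemplar constellations classify as expected", {
  p <- exemplar_profiles()
  expect_match(classify_profile(p$astro_r132s)$label, "^astrocytoma, IDH-mutant$")
  expect_match(classify_profile(p$oligo)$label, "oligodendroglioma")
  expect_match(classify_profile(p$midline)$label, "diffuse midline glioma")
  expect_match(classify_profile(p$gbm)$label, "glioblastoma, IDH-wildtype")
})

test_that("grade-4 marker, caveats and atypical combinations are surfaced", {
  astro4 <- molecular_profile(idh = "mutant-canonical-R132H",
                              codeletion = "not-codeleted",
                              cdkn2a = "homozygous-deletion")
  d <- classify_profile(astro4)
  expect_match(d$label, "grade 4 marker")
  expect_true(any(grepl("rule-3a", d$rule_trace)))

  # ATRX loss supports astrocytoma, caveats oligodendroglioma
  astro <- molecular_profile(idh = "mutant-canonical-R132H",
                             codeletion = "not-codeleted", atrx = "truncating")
  expect_true(any(grepl("ATRX", classify_profile(astro)$rule_trace)))
  oligo_atrx <- molecular_profile(idh = "mutant-canonical-R132H",
                                  codeletion = "codeleted", atrx = "truncating")
  expect_true(any(grepl("ATRX", classify_profile(oligo_atrx)$caveats)))

  # the rare codeleted IDH-wildtype glioblastoma: caveat, not an error
  odd <- molecular_profile(idh = "wild-type", tert = "mutant",
                           codeletion = "codeleted")
  d2 <- classify_profile(odd)
  expect_match(d2$label, "glioblastoma")
  expect_true(any(grepl("atypical", d2$caveats)))

  # nothing assessed -> not classifiable, with a caveat
  d3 <- classify_profile(molecular_profile())
  expect_match(d3$label, "not-classifiable")
  expect_gt(length(d3$caveats), 0)
})

test_that("classification is a pure function firing exactly one label over the full sweep", {
  idh_states <- list("mutant-canonical-R132H", "mutant-noncanonical",
                     "wild-type", marker(NA_character_, "not-assessed"))
  codel_states <- list("codeleted", "not-codeleted",
                       marker(NA_character_, "failed-QC"))
  h3_states <- list("K27M", "wild-type", marker(NA_character_, "not-assessed"))
  tert_states <- list("mutant", "wild-type", marker(NA_character_, "not-assessed"))
  egfr_states <- list("amplification", "neutral", marker(NA_character_, "not-assessed"))
  sig_states <- list("present", "partial", "absent",
                     marker(NA_character_, "not-assessed"))
  cdkn_states <- list("homozygous-deletion", "neutral",
                      marker(NA_character_, "not-assessed"))
  grid <- expand.grid(i = seq_along(idh_states), c = seq_along(codel_states),
                      h = seq_along(h3_states), t = seq_along(tert_states),
                      e = seq_along(egfr_states), s = seq_along(sig_states),
                      k = seq_along(cdkn_states))
  labels <- character(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    prof <- molecular_profile(idh = idh_states[[grid$i[r]]],
                              codeletion = codel_states[[grid$c[r]]],
                              h3 = h3_states[[grid$h[r]]],
                              tert = tert_states[[grid$t[r]]],
                              egfr = egfr_states[[grid$e[r]]],
                              plus7_minus10 = sig_states[[grid$s[r]]],
                              cdkn2a = cdkn_states[[grid$k[r]]])
    d1 <- classify_profile(prof)
    expect_length(d1$label, 1)
    expect_true(d1$label != "not-classifiable-by-molecular-criteria" ||
                  length(d1$caveats) > 0)
    labels[r] <- d1$label
    if (r %% 500 == 0) {
      expect_identical(classify_profile(prof)$label, d1$label)  # purity
    }
  }
  expect_true(all(nzchar(labels)))
})

test_that("markers a rule did not consult never change its label (ablation)", {
  set.seed(71)
  p <- exemplar_profiles()
  # midline diagnosis only consults H3: ablate everything else
  base <- classify_profile(p$midline)$label
  ablated <- molecular_profile(h3 = "K27M", idh = marker(NA, "not-assessed"),
                               tert = marker(NA, "not-assessed"))
  expect_identical(classify_profile(ablated)$label, base)
  # GBM rule consulted TERT and +7/-10, not MGMT
  gbm2 <- molecular_profile(idh = "wild-type", tert = "mutant",
                            plus7_minus10 = "present", mgmt = "high")
  expect_identical(classify_profile(gbm2)$label, classify_profile(p$gbm)$label)
})

test_that("actionability maps alterations to the bundled trial table", {
  braf <- molecular_profile(alterations = data.frame(
    gene = "BRAF", alteration = "p.V600E", class = "mutation", vaf = 0.30,
    cn = NA_real_, pathogenic = TRUE, hotspot = TRUE))
  rep1 <- actionable_report(braf)
  expect_true(rep1$actionable)
  expect_true("NCT04201457" %in% rep1$rows$trial)
  expect_true(all(rep1$rows$trial %in% trial_mapping()$trial))

  pdgfra <- molecular_profile(alterations = data.frame(
    gene = "PDGFRA", alteration = "amplification", class = "amplification",
    vaf = NA_real_, cn = 12, pathogenic = NA, hotspot = NA))
  rep2 <- actionable_report(pdgfra)
  expect_identical(rep2$rows$trial, "NCT02626364")
  expect_identical(rep2$rows$agent, "Crenolanib")

  expect_false(actionable_report(molecular_profile())$actionable)
  expect_equal(nrow(actionable_report(molecular_profile())$rows), 0)

  # sub-threshold hotspot mutations are not actionable
  low <- molecular_profile(alterations = data.frame(
    gene = "BRAF", alteration = "p.V600E", class = "mutation", vaf = 0.05,
    cn = NA_real_, pathogenic = FALSE, hotspot = TRUE))
  expect_false(actionable_report(low)$actionable)
  # genes outside the mapping are ignored
  other <- molecular_profile(alterations = data.frame(
    gene = "RB1", alteration = "p.X100*", class = "mutation", vaf = 0.4,
    cn = NA_real_, pathogenic = TRUE, hotspot = FALSE))
  expect_false(actionable_report(other)$actionable)
})

test_that("cohort summaries do exact bookkeeping against generator truth", {
  truths <- simulate_cohort(n = 60, seed = 73)
  expect_equal(as.integer(table(vapply(truths, `[[`, character(1), "subtype"))[
    c("glioblastoma", "astrocytoma", "oligodendroglioma", "ganglioglioma",
      "gliosarcoma", "midline_glioma")]),
    c(44L, 5L, 5L, 4L, 1L, 1L))

  samples <- lapply(truths, function(tr) {
    prof <- truth_profile(tr)
    list(profile = prof, diagnosis = classify_profile(prof),
         report = actionable_report(prof))
  })
  sm <- cohort_summary(samples)
  expect_equal(sm$n, 60)

  # marker bookkeeping equals direct counting over the truth profiles
  idh_truth <- sum(vapply(truths, function(tr)
    !is.null(tr$variants) && any(tr$variants$gene %in% c("IDH1", "IDH2")),
    logical(1)))
  expect_equal(sm$marker_counts$positive[sm$marker_counts$marker == "idh"],
               idh_truth)
  tert_truth <- sum(vapply(truths, function(tr)
    !is.null(tr$variants) && any(tr$variants$gene == "TERT"), logical(1)))
  expect_equal(sm$marker_counts$positive[sm$marker_counts$marker == "tert"],
               tert_truth)
  act_truth <- sum(vapply(samples, function(s) s$report$actionable, logical(1)))
  expect_equal(sm$actionability$numerator, act_truth)
  expect_equal(sm$actionability$rate, act_truth / 60)
  expect_equal(dim(sm$alteration_matrix)[2], 60)

  # single sample and empty cohort degenerate cleanly
  one <- cohort_summary(samples[1])
  expect_true(all(one$marker_counts$positive %in% 0:1))
  expect_equal(cohort_summary(list())$n, 0)

  # 22/60 example arithmetic
  flags <- c(rep(TRUE, 22), rep(FALSE, 38))
  fake <- lapply(flags, function(f) list(
    profile = molecular_profile(), diagnosis = classify_profile(molecular_profile()),
    report = structure(list(rows = NULL, actionable = f, n_qualifying = 0),
                       class = "actionability_report")))
  expect_equal(round(100 * cohort_summary(fake)$actionability$rate, 1), 36.7)
})
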