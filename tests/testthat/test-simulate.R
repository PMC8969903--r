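test_that("generators are deterministic under a fixed seed", {
  panel <- tiny_panel()
  tr <- truth_spec(purity = 0.6,
                   region_states = c(`1p` = "monoallelic-loss", `19q` = "diploid",
                                     chr7 = "gain", chr10 = "diploid"),
                   gene_cn = c(EGFR = 8), mgmt_methylation = 0.4)
  expect_identical(simulate_snp_counts(tr, panel, seed = 1),
                   simulate_snp_counts(tr, panel, seed = 1))
  expect_identical(simulate_coverage(tr, panel, seed = 1),
                   simulate_coverage(tr, panel, seed = 1))
  expect_identical(simulate_bisulfite_counts(tr, seed = 1),
                   simulate_bisulfite_counts(tr, seed = 1))
  expect_identical(simulate_fish_tallies(c("1O/2G" = 0.3), seed = 1),
                   simulate_fish_tallies(c("1O/2G" = 0.3), seed = 1))
  expect_false(identical(simulate_coverage(tr, panel, seed = 1),
                         simulate_coverage(tr, panel, seed = 2)))
})

test_that("SNP BAFs follow the purity closed forms", {
  # at purity 0 there is no tumor signal: heterozygous SNPs sit near 0.5
  panel <- arm_panel(45, "1p")
  tr0 <- truth_spec(purity = 0,
                    region_states = c(`1p` = "monoallelic-loss", `19q` = "diploid",
                                      chr7 = "diploid", chr10 = "diploid"))
  obs0 <- simulate_snp_counts(tr0, panel, depth = 500, seed = 90)
  het0 <- obs0$baf > 0.2 & obs0$baf < 0.8
  expect_equal(mean(obs0$baf[het0]), 0.5, tolerance = 0.02)

  # at purity 1 heterozygous SNPs under loss collapse toward 0/1
  tr1 <- truth_spec(purity = 1,
                    region_states = c(`1p` = "monoallelic-loss", `19q` = "diploid",
                                      chr7 = "diploid", chr10 = "diploid"))
  obs1 <- simulate_snp_counts(tr1, panel, depth = 500, seed = 91)
  expect_true(all(obs1$baf < 0.1 | obs1$baf > 0.9))

  # purity 0.6: folded heterozygous BAF ~ (1-a)/(2-a) = 0.286 within
  # binomial error (3 SE over ~22 het SNPs at depth 500)
  tr6 <- truth_spec(purity = 0.6,
                    region_states = c(`1p` = "monoallelic-loss", `19q` = "diploid",
                                      chr7 = "diploid", chr10 = "diploid"))
  baf_means <- vapply(1:50, function(r) {
    obs <- simulate_snp_counts(tr6, panel, depth = 500, seed = 9200 + r)
    het <- obs$baf > 0.1 & obs$baf < 0.9
    mean(pmin(obs$baf[het], 1 - obs$baf[het]))
  }, numeric(1))
  expect_equal(mean(baf_means), 0.4 / 1.4, tolerance = 0.005)
})

test_that("coverage follows the purity-mixture expectation", {
  panel <- tiny_panel()
  # CN 2 everywhere with no noise: flat profile, MAPD 0
  flat <- simulate_coverage(truth_spec(purity = 0.5), panel, 500,
                            noise_sd = 0, seed = 93)
  expect_true(all(flat == 500))
  bl <- build_baseline(matrix(rep(flat, 10), ncol = 10), panel)
  expect_equal(compute_mapd(normalize_coverage(flat, bl))$mapd, 0)

  # EGFR CN 20 at purity 0.7: the generator's expected relative coverage is
  # the purity mixture (0.7*20 + 0.3*2)/2 = 7.3, i.e. log2 ratio 2.87
  # against the diploid mean depth
  idx <- panel$amplicons$gene == "EGFR"
  meds <- vapply(1:30, function(r) {
    x <- simulate_coverage(truth_spec(purity = 0.7, gene_cn = c(EGFR = 20)),
                           panel, 500, 0.1, seed = 9300 + r)
    median(log2(x[idx] / 500))
  }, numeric(1))
  expect_equal(mean(meds), log2((0.7 * 20 + 0.3 * 2) / 2), tolerance = 0.05)

  # noise close to the simulator's log-normal model: MAPD ~ 0.954 * sd
  mapds <- vapply(1:40, function(r) {
    x <- simulate_coverage(truth_spec(purity = 0), panel, 500, 0.23,
                           seed = 9400 + r)
    compute_mapd(normalize_coverage(x, bl))$mapd
  }, numeric(1))
  expect_equal(mean(mapds), sqrt(2) * qnorm(0.75) * 0.23, tolerance = 0.02)
})

test_that("bisulfite counts respect methylation and conversion efficiency", {
  # m = 0 with perfect conversion: no retained C; m = 1: fully retained
  c0 <- simulate_bisulfite_counts(truth_spec(mgmt_methylation = 0,
                                             conversion_efficiency = 1),
                                  depth = 500, seed = 94)
  expect_true(all(c0$retained_c[c0$context == "CpG"] == 0))
  c1 <- simulate_bisulfite_counts(truth_spec(mgmt_methylation = 1),
                                  depth = 500, seed = 95)
  expect_true(all(c1$retained_c[c1$context == "CpG"] == 500))

  # m = 0.3 at depth 1000: called average within 2 points of 30%
  avg <- vapply(1:30, function(r) {
    call_mgmt(simulate_bisulfite_counts(
      truth_spec(mgmt_methylation = 0.3, conversion_efficiency = 1),
      depth = 1000, seed = 9500 + r))$average_pct
  }, numeric(1))
  expect_true(all(abs(avg - 30) < 2))
})

test_that("FISH tally generation matches requested fractions and QC gates", {
  t <- simulate_fish_tallies(c("1O/2G" = 0.35), n_nuclei = 2000, seed = 96)
  expect_equal(mean(t$orange == 1 & t$green == 2), 0.35, tolerance = 0.04)

  # a clearly codeleted tumor must satisfy both the pattern fraction and
  # the overall-ratio criterion; with a diploid background that requires a
  # deletion-pattern fraction comfortably above 0.6 (ratio = (2 - f)/2)
  hits <- vapply(1:100, function(r) {
    tt <- simulate_fish_tallies(c("1O/2G" = 0.70), n_nuclei = 200,
                                seed = 9600 + r)
    score_1p19q(tt, tt)$verdict
  }, character(1))
  expect_gte(mean(hits == "codeleted"), 0.99)

  none <- simulate_fish_tallies(c("1O/2G" = 0), n_nuclei = 300, seed = 97)
  expect_equal(score_1p19q(none, none)$verdict, "not-codeleted")

  small <- simulate_fish_tallies(c("1O/2G" = 0.5), n_nuclei = 199, seed = 98)
  expect_equal(score_1p19q(small, small)$verdict, "not-evaluable")

  expect_error(simulate_fish_tallies(c("1O/2G" = 0.7, "2O/2G" = 0.5), seed = 99),
               "more than 1")
  expect_error(simulate_fish_tallies(c("bad" = 0.5), seed = 99), "pattern")
})

test_that("cohorts have the requested composition and reproducible truth", {
  expect_length(simulate_cohort(n = 0, seed = 1), 0)
  co <- simulate_cohort(n = 60, seed = 100)
  expect_length(co, 60)
  expect_identical(co, simulate_cohort(n = 60, seed = 100))
  subtypes <- vapply(co, `[[`, character(1), "subtype")
  expect_equal(sum(subtypes == "glioblastoma"), 44)
  expect_true(all(vapply(co, function(tr) tr$purity >= 0.4 && tr$purity <= 0.9,
                         logical(1))))
  # truth-implied profiles classify to the matching subtype for the
  # canonical constellations
  oligo <- co[subtypes == "oligodendroglioma"][[1]]
  expect_match(classify_profile(truth_profile(oligo))$label, "oligodendroglioma")
  gbm <- co[subtypes == "glioblastoma"][[1]]
  expect_match(classify_profile(truth_profile(gbm))$label, "glioblastoma")
})
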