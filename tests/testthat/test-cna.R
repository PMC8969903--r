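make_baseline <- function(panel, n = 10, depth = 500, noise = 0.1,
                          seed0 = 9000) {
  counts <- vapply(seq_len(n), function(j) {
    simulate_coverage(truth_spec(purity = 0), panel, depth, noise,
                      seed = seed0 + j)
  }, numeric(nrow(panel$amplicons)))
  build_baseline(counts, panel)
}

test_that("normalization recovers known per-amplicon factors", {
  panel <- tiny_panel()
  n <- nrow(panel$amplicons)
  flat <- matrix(500, n, 10)
  bl <- build_baseline(flat, panel)

  # sample equal to the baseline -> all ratios 0
  r0 <- normalize_coverage(rep(500, n), bl)
  expect_true(all(abs(r0) < 1e-6))

  # doubling one amplicon's relative coverage -> its ratio ~ 1
  x <- rep(500, n); x[7] <- 1000
  r <- normalize_coverage(x, bl)
  expect_equal(r[7], 1, tolerance = 0.01)

  # arbitrary known factors recovered within 0.01 log2
  set.seed(2); fac <- exp(stats::runif(n, -0.5, 0.5))
  r2 <- normalize_coverage(round(500 * fac * 40), bl)  # scaled: total cancels
  expect_equal(r2 - mean(r2), log2(fac) - mean(log2(fac)), tolerance = 0.01)

  expect_error(normalize_coverage(rep(0, n), bl), "zero total")
})

test_that("MAPD matches closed forms and gates at 0.45", {
  expect_equal(compute_mapd(rep(0.3, 50))$mapd, 0)
  expect_true(compute_mapd(rep(0.3, 50))$evaluable)
  # alternating +d/-d: every adjacent difference is 2d
  d <- 0.12
  alt <- rep(c(d, -d), 100)
  expect_equal(compute_mapd(alt)$mapd, 2 * d)
  expect_false(compute_mapd(c(0.1))$evaluable)  # < 2 amplicons

  # invariance under constant shift
  set.seed(4); x <- rnorm(500, 0, 0.2)
  expect_equal(compute_mapd(x)$mapd, compute_mapd(x + 3)$mapd)

  # i.i.d. Gaussian ratios: MAPD ~ median|N(0, 2 sigma^2)| = 0.954 sigma,
  # so sigma = 0.5/0.954 puts MAPD ~ 0.5, above the gate
  sigma <- 0.5 / (sqrt(2) * qnorm(0.75))
  mapds <- vapply(1:50, function(i) {
    set.seed(100 + i); compute_mapd(rnorm(2000, 0, sigma))$mapd
  }, numeric(1))
  expect_equal(mean(mapds), 0.5, tolerance = 0.02)
  expect_true(mean(mapds >= 0.45) > 0.95)
})

test_that("MAPD is non-decreasing in noise amplitude (in expectation)", {
  mean_mapd <- function(sigma) {
    mean(vapply(1:20, function(i) {
      set.seed(200 + i); compute_mapd(rnorm(1000, 0, sigma))$mapd
    }, numeric(1)))
  }
  m <- vapply(c(0.05, 0.15, 0.3, 0.6), mean_mapd, numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("baseline building floors dispersion, is seeded-reproducible, and flags outliers", {
  panel <- tiny_panel()
  n <- nrow(panel$amplicons)
  flat <- matrix(500, n, 10)
  bl <- build_baseline(flat, panel)
  expect_true(all(bl$log2_sd >= 1e-3))
  expect_equal(bl$mean_rel, rep(1, n))
  expect_error(build_baseline(flat[, 1, drop = FALSE], panel), "at least")

  bl1 <- make_baseline(panel, seed0 = 9000)
  bl2 <- make_baseline(panel, seed0 = 9000)
  expect_identical(bl1, bl2)
  expect_false(any(bl1$loo_flagged))

  # contaminate the baseline with an amplified sample: leave-one-out flags it
  counts <- vapply(1:10, function(j)
    simulate_coverage(truth_spec(purity = 0), panel, 500, 0.1, seed = 9100 + j),
    numeric(n))
  counts[, 4] <- simulate_coverage(
    truth_spec(purity = 0.9, gene_cn = c(EGFR = 20)), panel, 500, 0.1,
    seed = 9104)
  bl3 <- build_baseline(counts, panel)
  expect_true(bl3$loo_flagged[4])
})

test_that("gene CNA calls recover simulated amplification and deletion", {
  panel <- tiny_panel()
  bl <- make_baseline(panel)

  # all ratios ~0 -> CN ~2, neutral
  neutral <- call_cna_profile(
    simulate_coverage(truth_spec(purity = 0), panel, 500, 0.1, seed = 31),
    bl, panel, genes = c("EGFR", "CDKN2A", "PTEN"))
  for (g in names(neutral$calls)) {
    expect_equal(neutral$calls[[g]]$cn, 2, tolerance = 0.2)
    expect_equal(neutral$calls[[g]]$call, "neutral")
  }

  # EGFR at 20 copies, purity 0.7 -> amplification, confidence above the gate
  amp <- call_cna_profile(
    simulate_coverage(truth_spec(purity = 0.7, gene_cn = c(EGFR = 20)),
                      panel, 500, 0.1, seed = 32),
    bl, panel, genes = "EGFR")
  expect_equal(amp$calls$EGFR$call, "amplification")
  expect_false(amp$calls$EGFR$filtered)

  # CDKN2A biallelic loss at purity 0.8 -> homozygous deletion;
  # monoallelic -> hemizygous loss
  hom <- call_cna_profile(
    simulate_coverage(truth_spec(purity = 0.8, gene_cn = c(CDKN2A = 0)),
                      panel, 500, 0.1, seed = 33),
    bl, panel, genes = "CDKN2A")
  expect_equal(hom$calls$CDKN2A$call, "homozygous-deletion")
  hemi <- call_cna_profile(
    simulate_coverage(truth_spec(purity = 0.8, gene_cn = c(CDKN2A = 1)),
                      panel, 500, 0.1, seed = 34),
    bl, panel, genes = "CDKN2A")
  expect_equal(hemi$calls$CDKN2A$call, "hemizygous-loss")

  expect_error(call_gene_cna(rep(0, nrow(panel$amplicons)), bl, "NOSUCH",
                             panel, compute_mapd(rep(0, 10))), "not on the panel")
})

test_that("a failed MAPD gate yields not-assessed, and baseline samples self-call CN 2", {
  panel <- tiny_panel()
  bl <- make_baseline(panel)
  noisy <- simulate_coverage(truth_spec(purity = 0), panel, 500,
                             noise_sd = 0.6, seed = 35)
  pr <- call_cna_profile(noisy, bl, panel, genes = "EGFR")
  expect_false(pr$qc$evaluable)
  expect_equal(pr$calls$EGFR$status, "not-assessed")
  expect_true(is.na(pr$calls$EGFR$cn))

  # baseline-like samples self-call CN ~ 2: per-gene median log2 is
  # unbiased (mean over replicates within 0.05 of 0) and each individual
  # call stays neutral
  genes <- c("EGFR", "CDKN2A", "PTEN", "BRAF", "PDGFRA")
  meds <- vapply(1:20, function(r) {
    self <- call_cna_profile(
      simulate_coverage(truth_spec(purity = 0), panel, 500, 0.1, seed = 36 + r),
      bl, panel, genes = genes)
    vapply(self$calls, function(cc) {
      expect_equal(cc$call, "neutral")
      cc$median_log2
    }, numeric(1))
  }, numeric(length(genes)))
  expect_true(all(abs(rowMeans(meds)) < 0.05))
})

test_that("calls are monotone in simulated true copy number", {
  panel <- tiny_panel()
  bl <- make_baseline(panel)
  rank_of <- c("homozygous-deletion" = 1, "hemizygous-loss" = 2, neutral = 3,
               gain = 4, amplification = 5)
  calls <- vapply(c(0, 1, 2, 4, 20), function(cn) {
    pr <- call_cna_profile(
      simulate_coverage(truth_spec(purity = 0.9, gene_cn = c(EGFR = cn)),
                        panel, 500, 0.08, seed = 40 + cn),
      bl, panel, genes = "EGFR")
    pr$calls$EGFR$call
  }, character(1))
  expect_true(all(diff(rank_of[calls]) >= 0))
})
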