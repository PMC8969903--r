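# Shared fixtures and independent oracles, all built in code.

# small panel: quick to simulate, still has every gene the callers touch
tiny_panel <- function(n_amplicons = 300) {
  synthetic_panel(genes = c(EGFR = 30, CDKN2A = 12, PTEN = 20, BRAF = 10,
                            PDGFRA = 10, TERT = 4),
                  n_amplicons = n_amplicons)
}

# arm-only panel for LOH recovery simulations (one region, n SNPs)
arm_panel <- function(n_snps = 45, region = "1p") {
  amplicons <- data.frame(chrom = "chr20", start = seq(1e6, by = 500, length.out = 10),
                          end = seq(1e6, by = 500, length.out = 10) + 180,
                          pool = "pool1", gene = "FILLER",
                          stringsAsFactors = FALSE)
  counts <- stats::setNames(c(0, 0, 0, 0), c("1p", "19q", "chr7", "chr10"))
  counts[region] <- n_snps
  snps <- data.frame(
    rsid = paste0("rs", seq_len(sum(counts))),
    chrom = rep(c("chr1", "chr19", "chr7", "chr10"), counts),
    pos = seq_len(sum(counts)) * 1e5,
    region = rep(names(counts), counts), stringsAsFactors = FALSE)
  panel_design(amplicons, snps)
}

random_variants <- function(n, seed) {
  set.seed(seed)
  data.frame(
    chrom = sample(paste0("chr", 1:22), n, replace = TRUE),
    pos = sample.int(1e8, n),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    vaf = round(stats::runif(n, 0, 0.2), 4),
    depth = sample(50:500, n, replace = TRUE),
    quality = round(stats::runif(n, 20, 80), 1),
    pvalue = 10^stats::runif(n, -8, 0),
    gene = sample(c("IDH1", "TP53", "EGFR", "PTEN"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# brute-force re-statement of the four retention predicates, written
# independently of filter_variants()
oracle_retained <- function(v, th = default_config()$variant) {
  ok <- rep(TRUE, nrow(v))
  for (i in seq_len(nrow(v))) {
    r <- v[i, ]
    if (is.na(r$vaf) || is.na(r$depth) || is.na(r$quality) || is.na(r$pvalue)) {
      ok[i] <- FALSE
    } else {
      ok[i] <- r$vaf >= th$min_vaf && r$depth > th$min_depth &&
        r$quality > th$min_quality && r$pvalue < th$max_pvalue
    }
  }
  ok
}

# independent interval oracle for the BAF windows
oracle_baf_state <- function(baf) {
  if (baf <= 0.05 || baf >= 0.95) return("homozygous")
  if (baf >= 0.45 && baf <= 0.60) return("balanced")
  "imbalanced"
}

# independent textbook kappa: build the full 2x2 matrix and use marginals
oracle_kappa <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)  # rows CT, cols NGS
  n <- sum(m)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  (po - pe) / (1 - pe)
}

# brute-force FISH evaluator: re-reads the published rules directly
oracle_fish <- function(tallies, assay) {
  n <- nrow(tallies)
  if (n < 200) return("not-evaluable")
  ratio_tot <- {
    keep <- tallies$green > 0
    if (any(keep)) sum(tallies$orange[keep]) / sum(tallies$green[keep]) else NA
  }
  if (assay == "arm") {          # one probe set of the 1p/19q pair
    frac <- sum(tallies$orange == 1 & tallies$green == 2) / n
    if (frac >= 0.30 && !is.na(ratio_tot) && ratio_tot <= 0.70) "positive" else "negative"
  } else if (assay == "egfr") {
    nhigh <- 0
    for (i in seq_len(n)) {
      if (tallies$cluster[i] ||
          (tallies$green[i] > 0 && tallies$orange[i] / tallies$green[i] > 2)) {
        nhigh <- nhigh + 1
      }
    }
    if (nhigh / n > 0.10) "amplified"
    else if (!is.na(ratio_tot) && ratio_tot > 1 && ratio_tot <= 2) "gain"
    else "normal"
  } else if (assay == "chr7") {
    if (sum(tallies$orange == 3 & tallies$green == 3) / n >= 0.30) "gain" else "normal"
  } else if (assay == "chr10") {
    if (sum(tallies$orange == 1 & tallies$green == 1) / n >= 0.30) "loss" else "normal"
  } else if (assay == "cdkn2a") {
    if (sum(tallies$orange == 0 & tallies$green >= 1) / n >= 0.20)
      "homozygous-deletion" else "no-homozygous-deletion"
  }
}

random_tallies <- function(n_nuclei, seed) {
  set.seed(seed)
  data.frame(nucleus = seq_len(n_nuclei), probe_set = "probe",
             orange = sample(0:6, n_nuclei, replace = TRUE,
                             prob = c(1, 3, 6, 2, 1, 1, 1)),
             green = sample(0:4, n_nuclei, replace = TRUE,
                            prob = c(1, 4, 8, 2, 1)),
             cluster = stats::runif(n_nuclei) < 0.02,
             stringsAsFactors = FALSE)
}
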