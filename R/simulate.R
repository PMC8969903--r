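#' Synthetic panel design
#'
#' A scaled version of the assay layout for simulation and testing:
#' amplicons tiled over the relevant chromosomes with a configurable count
#' per gene, and a SNP manifest with 45 SNPs tagged 1p/19q and 25 tagged
#' chr7/chr10 (matching the assay's 70 LOH SNPs).
#'
#' @param genes named integer vector: amplicons per gene. The default lays
#'   out diagnostic and actionable genes over ~`n_amplicons` amplicons.
#' @param n_amplicons approximate total amplicons; filler amplicons on a
#'   neutral background gene pad the panel to this size.
#' @param n_1p,n_19q,n_chr7,n_chr10 SNPs per region.
#' @return a `panel_design`.
#' @export
synthetic_panel <- function(genes = c(EGFR = 30, CDKN2A = 12, PTEN = 20,
                                      IDH1 = 10, ATRX = 35, TP53 = 15,
                                      BRAF = 18, PDGFRA = 22, CDK4 = 8,
                                      MET = 21, PIK3CA = 20, TERT = 4),
                            n_amplicons = 2361,
                            n_1p = 23, n_19q = 22, n_chr7 = 13, n_chr10 = 12) {
  gene_chrom <- c(EGFR = "chr7", CDKN2A = "chr9", PTEN = "chr10",
                  IDH1 = "chr2", ATRX = "chrX", TP53 = "chr17",
                  BRAF = "chr7", PDGFRA = "chr4", CDK4 = "chr12",
                  MET = "chr7", PIK3CA = "chr3", TERT = "chr5")
  n_filler <- max(0, n_amplicons - sum(genes))
  all_genes <- c(rep(names(genes), genes), rep("FILLER", n_filler))
  chroms <- c(rep(unname(gene_chrom[names(genes)]), genes),
              rep("chr20", n_filler))
  n <- length(all_genes)
  start <- seq(1e6, by = 500, length.out = n)
  amplicons <- data.frame(chrom = chroms, start = start, end = start + 180,
                          pool = paste0("pool", (seq_len(n) %% 3) + 1),
                          gene = all_genes, stringsAsFactors = FALSE)
  # order by chromosome then position, the genomic order MAPD assumes
  amplicons <- amplicons[order(amplicons$chrom, amplicons$start), ]
  rownames(amplicons) <- NULL

  region <- rep(c("1p", "19q", "chr7", "chr10"),
                c(n_1p, n_19q, n_chr7, n_chr10))
  snps <- data.frame(
    rsid = paste0("rs", 100000 + seq_along(region)),
    chrom = c("chr1", "chr19", "chr7", "chr10")[match(region, REGION_TAGS)],
    pos = seq(2e6, by = 1e5, length.out = length(region)),
    region = region, stringsAsFactors = FALSE)
  panel_design(amplicons, snps)
}

#' Truth specification for a simulated sample
#'
#' @param sample_id identifier.
#' @param purity tumor cell fraction in [0,1].
#' @param region_states named character vector over `"1p"`, `"19q"`,
#'   `"chr7"`, `"chr10"`: `"diploid"`, `"monoallelic-loss"` or `"gain"`.
#' @param gene_cn named numeric vector of true tumor copy numbers for any
#'   non-diploid genes (others default to 2).
#' @param variants data.frame of true somatic variants (`gene`, `hgvs_c`,
#'   `hgvs_p`, `vaf`).
#' @param mgmt_methylation true methylated fraction at the four CpG sites
#'   (length 1 or 4).
#' @param conversion_efficiency bisulfite conversion efficiency.
#' @param fish_fractions named list per assay of pattern fractions, e.g.
#'   `list(p1p = c("1O/2G" = 0.4, "2O/2G" = 0.6))`.
#' @return a `truth_spec` list.
#' @export
truth_spec <- function(sample_id = "synthetic",
                       purity = 0.6,
                       region_states = c(`1p` = "diploid", `19q` = "diploid",
                                         chr7 = "diploid", chr10 = "diploid"),
                       gene_cn = numeric(0),
                       variants = NULL,
                       mgmt_methylation = 0,
                       conversion_efficiency = 0.99,
                       fish_fractions = list()) {
  stopifnot(purity >= 0, purity <= 1)
  structure(list(sample_id = sample_id, purity = purity,
                 region_states = region_states, gene_cn = gene_cn,
                 variants = variants,
                 mgmt_methylation = rep_len(mgmt_methylation, 4),
                 conversion_efficiency = conversion_efficiency,
                 fish_fractions = fish_fractions),
            class = "truth_spec")
}

#' Expected B-allele frequency of a heterozygous SNP under allelic change
#'
#' For tumor purity `a`, a heterozygous SNP losing one allele has expected
#' BAF (1-a)/(2-a) (lost allele) or 1/(2-a) (retained allele); a one-copy
#' gain gives 1/(2+a) or (1+a)/(2+a); a diploid region stays at 1/2.
#'
#' @param purity tumor purity in [0,1].
#' @param state `"diploid"`, `"monoallelic-loss"` or `"gain"`.
#' @param lost_b for loss: is the B allele the lost one; for gain: is the
#'   B allele the un-gained one.
#' @return expected BAF.
#' @export
expected_baf <- function(purity, state, lost_b = TRUE) {
  a <- purity
  switch(state,
    "diploid" = 0.5,
    "monoallelic-loss" = if (lost_b) (1 - a) / (2 - a) else 1 / (2 - a),
    "gain" = if (lost_b) 1 / (2 + a) else (1 + a) / (2 + a),
    abort("unknown region state '", state, "'"))
}

#' Simulate a SNP allele-depth table
#'
#' Germline genotypes are drawn per SNP (heterozygous with probability
#' `p_het`; the panel's SNPs are chosen to be highly polymorphic, so the
#' default is 0.5). Heterozygous SNPs in regions with an allelic change
#' have their expected BAF shifted by the purity-diluted state (see
#' [expected_baf()]); which parental allele is affected is random per arm
#' event. Read counts are binomial at the given depth, with a small
#' sequencing error rate keeping homozygous BAFs off exactly 0/1.
#'
#' @param truth a `truth_spec`.
#' @param panel a `panel_design`.
#' @param depth sequencing depth per SNP.
#' @param p_het heterozygosity probability per SNP.
#' @param error_rate base miscall rate.
#' @param seed integer seed (mandatory for reproducibility).
#' @return a `snp_observations` data.frame (see [read_snp_counts()]).
#' @export
simulate_snp_counts <- function(truth, panel, depth = 500, p_het = 0.5,
                                error_rate = 0.001, seed) {
  set.seed(seed)
  snps <- panel$snps
  n <- nrow(snps)
  het <- stats::runif(n) < p_het
  # phase is random per SNP: the affected haplotype carries the B allele at
  # roughly half the heterozygous sites, so BAFs split to both sides of 0.5
  baf <- vapply(seq_len(n), function(i) {
    if (!het[i]) {
      if (stats::runif(1) < 0.5) error_rate else 1 - error_rate
    } else {
      state <- truth$region_states[[snps$region[i]]]
      expected_baf(truth$purity, state, lost_b = stats::runif(1) < 0.5)
    }
  }, numeric(1))
  alt <- stats::rbinom(n, depth, baf)
  df <- data.frame(rsid = snps$rsid, ref_depth = depth - alt, alt_depth = alt,
                   stringsAsFactors = FALSE)
  snp_observations(df, panel)
}

#' Simulate an amplicon coverage vector
#'
#' Expected relative coverage of an amplicon scales with the purity mixture
#' (a * CN + (1-a) * 2) / 2 of its gene's true tumor copy number;
#' multiplicative log-normal noise with standard deviation `noise_sd` (in
#' log2 units) is applied per amplicon. Genes absent from `truth$gene_cn`
#' are diploid. Whole-chromosome states in `truth$region_states` (chr7 /
#' chr10) apply to all amplicons on that chromosome.
#'
#' @param truth a `truth_spec`.
#' @param panel a `panel_design`.
#' @param mean_depth mean reads per amplicon.
#' @param noise_sd per-amplicon log2 noise standard deviation.
#' @param seed integer seed.
#' @return integer vector of read counts in panel amplicon order.
#' @export
simulate_coverage <- function(truth, panel, mean_depth = 500, noise_sd = 0.15,
                              seed) {
  set.seed(seed)
  a <- truth$purity
  amp <- panel$amplicons
  cn <- rep(2, nrow(amp))
  chr_state <- function(chrom) {
    if (chrom %in% names(truth$region_states)) truth$region_states[[chrom]]
    else "diploid"
  }
  for (chrom in c("chr7", "chr10")) {
    st <- chr_state(chrom)
    if (st == "gain") cn[amp$chrom == chrom] <- 3
    if (st == "monoallelic-loss") cn[amp$chrom == chrom] <- 1
  }
  for (g in names(truth$gene_cn)) cn[amp$gene == g] <- truth$gene_cn[[g]]
  factor <- (a * cn + (1 - a) * 2) / 2
  counts <- mean_depth * factor * 2^stats::rnorm(nrow(amp), 0, noise_sd)
  pmax(0L, as.integer(round(counts)))
}

#' Simulate a bisulfite count table for the MGMT promoter
#'
#' Retained-C reads at each CpG site are binomial with success probability
#' m + (1-m)(1-e): a methylated cytosine is always read as C, an
#' unmethylated one escapes conversion with probability 1-e. Non-CpG
#' cytosines (methylation ~0) are converted at the efficiency rate.
#'
#' @param truth a `truth_spec` (`mgmt_methylation`, `conversion_efficiency`).
#' @param depth reads per site.
#' @param seed integer seed.
#' @return data.frame in the layout [call_mgmt()] consumes.
#' @export
simulate_bisulfite_counts <- function(truth, depth = 500, seed) {
  set.seed(seed)
  ref <- mgmt_reference()
  m <- truth$mgmt_methylation
  e <- truth$conversion_efficiency
  p_retained <- m + (1 - m) * (1 - e)
  cpg_retained <- stats::rbinom(4, depth, p_retained)
  non_retained <- stats::rbinom(length(ref$noncpg_c_positions), depth, 1 - e)
  rbind(
    data.frame(position = ref$cpg_positions, context = "CpG",
               retained_c = cpg_retained, converted_t = depth - cpg_retained,
               stringsAsFactors = FALSE),
    data.frame(position = ref$noncpg_c_positions, context = "non-CpG",
               retained_c = non_retained, converted_t = depth - non_retained,
               stringsAsFactors = FALSE))
}

parse_pattern <- function(pattern) {
  if (pattern == "cluster") return(list(orange = 15L, green = 2L, cluster = TRUE))
  m <- regmatches(pattern, regexec("^([0-9]+)O/([0-9]+)G$", pattern))[[1]]
  if (length(m) != 3) abort("bad FISH pattern '", pattern,
                            "' (use e.g. '1O/2G' or 'cluster')")
  list(orange = as.integer(m[2]), green = as.integer(m[3]), cluster = FALSE)
}

#' Simulate a FISH nucleus tally table
#'
#' Nuclei are drawn multinomially over signal patterns. Patterns are
#' strings like `"1O/2G"` (1 orange, 2 green) or `"cluster"` (innumerable
#' orange clusters); fractions must sum to <= 1, the remainder going to the
#' normal `"2O/2G"` pattern.
#'
#' @param pattern_fractions named numeric vector of pattern fractions.
#' @param n_nuclei number of nuclei (a valid assay needs >= 200).
#' @param probe_set probe-set label stored in the table.
#' @param seed integer seed.
#' @return tally data.frame (`nucleus`, `probe_set`, `orange`, `green`,
#'   `cluster`).
#' @export
simulate_fish_tallies <- function(pattern_fractions, n_nuclei = 200,
                                  probe_set = "probe", seed) {
  set.seed(seed)
  rest <- 1 - sum(pattern_fractions)
  if (rest < -1e-9) abort("pattern fractions sum to more than 1")
  fracs <- c(pattern_fractions, `2O/2G` = max(rest, 0))
  fracs <- tapply(fracs, names(fracs), sum)  # merge duplicate patterns
  counts <- as.vector(stats::rmultinom(1, n_nuclei, fracs))
  rows <- lapply(seq_along(counts), function(i) {
    if (counts[i] == 0) return(NULL)
    p <- parse_pattern(names(fracs)[i])
    data.frame(orange = rep(p$orange, counts[i]), green = p$green,
               cluster = p$cluster)
  })
  df <- do.call(rbind, rows)
  df <- df[sample.int(nrow(df)), , drop = FALSE]
  data.frame(nucleus = seq_len(nrow(df)), probe_set = probe_set,
             orange = df$orange, green = df$green, cluster = df$cluster,
             row.names = NULL, stringsAsFactors = FALSE)
}

COHORT_COMPOSITION <- c(glioblastoma = 44, astrocytoma = 5,
                        oligodendroglioma = 5, ganglioglioma = 4,
                        gliosarcoma = 1, midline_glioma = 1)

subtype_truth <- function(subtype, id, purity, seed) {
  set.seed(seed)
  regions <- c(`1p` = "diploid", `19q` = "diploid",
               chr7 = "diploid", chr10 = "diploid")
  gene_cn <- numeric(0)
  variants <- NULL
  add_var <- function(gene, hgvs_c, hgvs_p, vaf) {
    variants <<- rbind(variants, data.frame(
      gene = gene, hgvs_c = hgvs_c, hgvs_p = hgvs_p, vaf = vaf,
      stringsAsFactors = FALSE))
  }
  het_vaf <- purity / 2
  if (subtype == "oligodendroglioma") {
    regions[c("1p", "19q")] <- "monoallelic-loss"
    add_var("IDH1", "c.395G>A", "p.R132H", het_vaf)
  } else if (subtype == "astrocytoma") {
    add_var("IDH1", "c.395G>A", "p.R132H", het_vaf)
    add_var("ATRX", "c.2094del", "p.Lys698Ter", het_vaf)
    add_var("TP53", "c.818G>A", "p.R273H", het_vaf)
  } else if (subtype == "glioblastoma") {
    regions["chr7"] <- "gain"
    regions["chr10"] <- "monoallelic-loss"
    add_var("TERT", "c.1-124C>T", NA_character_, het_vaf)
    if (stats::runif(1) < 0.3) gene_cn <- c(EGFR = 20)
  } else if (subtype == "midline_glioma") {
    add_var("H3-3A", "c.83A>T", "p.K27M", het_vaf)
  } else if (subtype == "ganglioglioma") {
    if (stats::runif(1) < 0.5) add_var("BRAF", "c.1799T>A", "p.V600E", het_vaf)
  } else if (subtype == "gliosarcoma") {
    add_var("TP53", "c.437G>A", "p.Trp146Ter", het_vaf)
  }
  tr <- truth_spec(sample_id = id, purity = purity, region_states = regions,
                   gene_cn = gene_cn, variants = variants,
                   mgmt_methylation = stats::runif(1),
                   fish_fractions = list())
  tr$subtype <- subtype
  tr
}

#' Simulate a cohort of glioma samples with known truth
#'
#' Draws per-sample truth specifications following a diagnostic
#' composition (default: the 60-sample mix of 44 glioblastomas, 5
#' astrocytomas, 5 oligodendrogliomas, 4 gangliogliomas, 1 gliosarcoma and
#' 1 diffuse midline glioma), with purity uniform in [0.4, 0.9]. Each
#' truth determines the sample's marker states deterministically;
#' read-count data for any assay can then be generated with the per-assay
#' simulators using `truth` and the per-sample `seed` stored alongside.
#'
#' @param n cohort size; the composition is scaled/truncated to `n`.
#' @param composition named integer vector of subtype counts.
#' @param seed integer seed.
#' @return list of `truth_spec` objects (each with `$subtype` and `$seed`).
#' @export
simulate_cohort <- function(n = 60, composition = COHORT_COMPOSITION, seed = 1) {
  set.seed(seed)
  subtypes <- rep(names(composition), composition)
  if (n <= length(subtypes)) subtypes <- subtypes[seq_len(n)]
  else subtypes <- c(subtypes, sample(names(composition), n - length(subtypes),
                                      replace = TRUE))
  purities <- stats::runif(n, 0.4, 0.9)
  seeds <- sample.int(.Machine$integer.max %/% 2, n)
  lapply(seq_len(n), function(i) {
    tr <- subtype_truth(subtypes[i], sprintf("S%02d", i), purities[i], seeds[i])
    tr$seed <- seeds[i]
    tr
  })
}

#' Marker states implied by a truth specification
#'
#' The bookkeeping oracle for cohort-level tests: converts a `truth_spec`
#' into the `molecular_profile` its data would yield under noise-free
#' interpretation.
#'
#' @param truth a `truth_spec` from [simulate_cohort()].
#' @return a `molecular_profile`.
#' @export
truth_profile <- function(truth) {
  v <- truth$variants
  has <- function(gene, pat = "") {
    !is.null(v) && any(v$gene == gene &
                         grepl(pat, paste0(v$hgvs_p, v$hgvs_c)))
  }
  cn_of <- function(g) if (g %in% names(truth$gene_cn)) truth$gene_cn[[g]] else 2
  idh <- if (has("IDH1", "R132H")) "mutant-canonical-R132H"
         else if (has("IDH1") || has("IDH2")) "mutant-noncanonical"
         else "wild-type"
  codel <- if (truth$region_states[["1p"]] == "monoallelic-loss" &&
               truth$region_states[["19q"]] == "monoallelic-loss") "codeleted"
           else "not-codeleted"
  atrx <- if (has("ATRX")) "truncating" else "wild-type"
  tert <- if (has("TERT")) "mutant" else "wild-type"
  egfr_cn <- cn_of("EGFR")
  egfr_mix <- truth$purity * egfr_cn + (1 - truth$purity) * 2
  egfr <- if (egfr_mix > 4) "amplification" else if (egfr_mix > 2.5) "gain"
          else "neutral"
  sig <- if (truth$region_states[["chr7"]] == "gain" &&
             truth$region_states[["chr10"]] == "monoallelic-loss") "present"
         else if (truth$region_states[["chr7"]] == "gain" ||
                  truth$region_states[["chr10"]] == "monoallelic-loss") "partial"
         else "absent"
  cdkn2a_cn <- cn_of("CDKN2A")
  cdkn2a_mix <- truth$purity * cdkn2a_cn + (1 - truth$purity) * 2
  cdkn2a <- if (cdkn2a_mix < 0.5) "homozygous-deletion"
            else if (cdkn2a_mix < 1.5) "hemizygous-loss" else "neutral"
  h3 <- if (has("H3-3A", "K27M") || has("H3F3A", "K27M")) "K27M" else "wild-type"
  tp53 <- if (!is.null(v) && any(v$gene == "TP53" & is_truncating(v$hgvs_p)))
            "nonsense-truncating"
          else if (has("TP53")) "missense" else "none"
  mgmt <- classify_average(mean(truth$mgmt_methylation) * 100)

  alt <- empty_alterations()
  if (!is.null(v)) {
    keep <- v$gene %in% trial_mapping()$gene
    if (any(keep)) {
      vv <- v[keep, , drop = FALSE]
      alt <- rbind(alt, data.frame(
        gene = vv$gene, alteration = ifelse(is.na(vv$hgvs_p), vv$hgvs_c, vv$hgvs_p),
        class = "mutation", vaf = vv$vaf, cn = NA_real_,
        pathogenic = TRUE, hotspot = TRUE, stringsAsFactors = FALSE))
    }
  }
  for (g in names(truth$gene_cn)) {
    cls <- if (truth$gene_cn[[g]] > 2) "amplification" else "deletion"
    alt <- rbind(alt, data.frame(gene = g, alteration = cls, class = cls,
                                 vaf = NA_real_, cn = truth$gene_cn[[g]],
                                 pathogenic = NA, hotspot = NA,
                                 stringsAsFactors = FALSE))
  }
  molecular_profile(idh = idh, codeletion = codel, atrx = atrx, tert = tert,
                    egfr = egfr, plus7_minus10 = sig, cdkn2a = cdkn2a,
                    h3 = h3, tp53 = tp53, mgmt = mgmt, alterations = alt,
                    sample_id = truth$sample_id)
}
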