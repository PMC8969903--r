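---
title: "Methods: tumor-only interpretation of a glioma DNA panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor-only interpretation of a glioma DNA panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliotyper)
```

This vignette explains the models and decision rules behind each caller,
the tunable parameters and why their defaults are what they are, what the
synthetic-data generators do and do not emulate, and the numerical and
design choices made where the problem left them open.

## The setting

The package interprets a tumor-only targeted amplicon panel: a few
thousand amplicons covering glioma-relevant genes, ~70 amplicons over
highly polymorphic SNPs on 1p, 19q, chromosome 7 and chromosome 10 for
loss-of-heterozygosity detection, and dedicated amplicons for the TERT
promoter and for four bisulfite-assayed CpG sites in the MGMT promoter.
There is no matched normal: every somatic signal is diluted by the
non-tumor cell fraction, so tumor purity $a$ appears in every closed form
below. All coordinates are 1-based inclusive on GRCh37/hg19; BED input is
converted on read and the conversion is its own inverse
(`read_panel()` / `write_panel_bed()`).

Every marker result carries a status — `called`, `not-assessed` or
`failed-QC` — because in routine practice different markers are assessable
in different subsets of samples; absence must be explicit, never a silent
negative. The integrated classifier and cohort summaries respect those
denominators.

## Variant filtering

A raw call is retained when VAF $\ge$ 3%, depth $> 100$, Phred quality
$> 40$ and caller $p < 10^{-4}$. The inequalities are implemented exactly
as stated; the VAF cutoff is inclusive so boundary calls at exactly 3%
are kept. Two deliberate choices:

* **Hotspot rescue.** Clinically unambiguous hotspots (BRAF V600E, IDH1
  codon 132, IDH2 codon 172, TERT c.1-124C>T / c.1-146C>T, H3-3A K27M)
  are retained down to 2% VAF. Low-purity or subclonal hotspot events are
  real and diagnostically decisive — a ganglioglioma's V600E at 2.5% VAF
  is the motivating case — while a generic 2% threshold would admit too
  much noise. The list ships as an editable TSV
  (`default_hotspots()`); the quality/depth/p-value gates still apply to
  rescued calls, since they guard sequencing artifacts, not biology.
* **Explicit exclusions.** Every removed record carries machine-readable
  reasons (`vaf-below-cutoff`, `missing-depth`, ...) that partition the
  removed set; filtering is idempotent and monotone in the VAF cutoff,
  and both properties are tested.

Pathogenicity is tier membership (tiers 1–3) in a user-supplied
annotation table; unannotated variants are never called pathogenic, and
in particular an unannotated ATRX missense is not treated as a loss
event — only truncating or tier-annotated ATRX variants are.

## SNP-BAF loss of heterozygosity

For a heterozygous SNP, the B-allele frequency in a tumor of purity $a$
under monoallelic loss is

$$\mathrm{BAF} = \frac{1-a}{2-a} \quad\text{or}\quad \frac{1}{2-a},$$

depending on which haplotype carries the B allele; under a one-copy gain
the analogous forms are $1/(2+a)$ and $(1+a)/(2+a)$. At $a = 0.6$ a lost
arm's heterozygous SNPs sit at 0.286/0.714 — far from both the
heterozygosity window and the homozygosity windows.

The windows are the assay's operating ranges: homozygous in
$[0, 0.05] \cup [0.95, 1]$, balanced heterozygous in $[0.45, 0.60]$, all
bounds inclusive, everything else imbalanced. The heterozygosity window
is **asymmetric** around 0.5 as printed; whether that reflects reference
bias in the original assay or not cannot be determined, so it is
implemented as stated and exposed in `default_config()$baf` for
laboratories that prefer a symmetric window. SNPs below 100× depth are
indeterminate (the one depth standard shared with variant filtering).

Arm aggregation is necessarily a design choice in tumor-only data,
because germline-homozygous SNPs carry no LOH signal: informative SNPs
are the balanced plus imbalanced ones, and an arm is called LOH when at
least 5 informative SNPs are present and at least 60% of them are
imbalanced. The floor protects against sparse arms; the majority rule
resists isolated noisy SNPs. Under the study conditions (45 SNPs for
1p+19q, depth 500), simulated sensitivity and specificity for monoallelic
loss exceed 95% across purities 0.4–0.9 (200 replicates per purity; see
`test-acceptance.R`).

BAF imbalance cannot tell gain from loss, so the +7/−10 signature
resolves direction from the chromosome's median coverage log2 ratio:
gain needs $> +0.1$, loss $< -0.1$ — roughly a single-copy change at 15%
purity, deliberately permissive because the BAF imbalance has already
established that something is wrong. Imbalance without coverage support
is reported as direction-unresolved, never assumed.

## Copy number and MAPD

Counts are normalized to relative coverage (mean 1 across amplicons) and
compared to a baseline of CNA-free samples (ten in the validated setup;
the code requires at least two and self-checks the set by leave-one-out,
flagging any member whose gene-level median |log2 ratio| exceeds 0.3
against the others). The per-amplicon ratio is
$\log_2\!\big((s_i + \varepsilon)/(\bar b_i + \varepsilon)\big)$ with
$\varepsilon$ equal to one read on the normalized scale, keeping
zero-count amplicons finite.

MAPD — the median over genomically adjacent amplicon pairs of
$|r_i - r_{i+1}|$ — gates the sample at $< 0.45$ (strict). The
adjacent-pair form is used, not the all-pairs reading of the acronym: the
adjacent form is the one with an established 0.45 operating gate, and it
is insensitive to true copy-number steps, which affect only the few pairs
at segment boundaries. For i.i.d. Gaussian noise of standard deviation
$\sigma$ the expected MAPD is $\sqrt{2}\,\Phi^{-1}(0.75)\,\sigma \approx
0.954\,\sigma$, the closed form the simulator tests assert.

A gene's estimate is $\mathrm{CN} = 2 \cdot 2^{\tilde r}$ with $\tilde r$
the median ratio over its amplicons. Call boundaries — CN > 4
amplification, 2.5–4 gain, 1.5–2.5 neutral, 0.5–1.5 hemizygous loss,
< 0.5 homozygous deletion — mirror the FISH semantics (ratio > 2 ⇒
amplification ⇒ CN > 4) so sequencing and FISH verdicts remain
commensurable in concordance analysis. The confidence score is
$-10\log_{10}p$ of the two-sided Gaussian test of the gene's mean ratio
against the baseline dispersion over its amplicons, so the gate at 30
corresponds to $p < 10^{-3}$; the underlying vendor score is proprietary,
and this open analogue reproduces the gate's semantics rather than its
exact values. Gated calls are emitted but flagged `filtered`. Note that a
truly neutral gene has low confidence by construction — the score
measures departure from CN 2, so the flag is meaningful for non-neutral
calls.

Total-read normalization slightly depresses all other amplicons when one
gene is massively amplified; on a ~2400-amplicon panel a 30-amplicon gene
at mixture CN 13 shifts the rest by ~0.1 log2, well inside the neutral
band. On much smaller panels this artifact grows — a known limitation of
library-size normalization without median re-centering.

## MGMT promoter methylation

The methylated fraction at each of the four CpG cytosines of the assayed
19-mer (`mgmt_reference()`; chr10:131,265,519–131,265,537) is
retained-C / (retained-C + converted-T). The sample average is the
unweighted mean over covered sites — four sites at comparable depth give
depth-weighting nothing to correct — and is banded: below 10%
unmethylated, 10–50% moderate (both bounds inclusive: "between 10 and
50" is read inclusively, "below" and "above" strictly), above 50% high.
Zero-coverage sites are excluded and listed; all four uncovered means
not-assessed.

Conversion efficiency is the pooled converted fraction at the five
non-CpG cytosines of the same 19-mer; the QC floor defaults to 98% — a
declared choice (essentially lossless conversion is expected of a
successful bisulfite reaction), not a published threshold. The Sanger
emulation scores a site methylated when the cytosine peak fraction
exceeds 20% — an exact 20% scores unmethylated, closing the gap left by
two strict inequalities — and averages per-site *ratios*, not binary
calls, before banding; averaging ratios keeps the Sanger and sequencing
averages on the same scale.

## FISH scoring

The four scorers apply the published thresholds verbatim (see the README
summary). Two clarifications the rules leave open: the EGFR
amplification criterion uses the *per-nucleus* ratio (> 2, or clusters,
in > 10% of nuclei) while the gain criterion uses the *overall*
orange/green ratio in (1, 2]; both ratios are computed and reported.
Nuclei with zero green signals have an undefined ratio: they are excluded
from all ratio computations, still count toward nucleus totals, and are
tallied in QC.

One structural observation, surfaced by the tests: for 1p/19q the overall
ratio criterion ($\le 0.70$) binds harder than the 30% pattern criterion.
With a diploid background, a deletion-pattern fraction $f$ gives an
overall ratio $(2-f)/2$, so both criteria hold jointly only when
$f \ge 0.6$; a tumor with 35% 1O/2G nuclei and a clean diploid remainder
fails the ratio. Real codeleted tumors pass because their non-1O/2G
nuclei also carry reduced orange counts. The recovery property is
therefore exercised at $f = 0.7$.

## Integrated classification

Rule precedence is fixed and total: H3-3A K27M first (a midline glioma
is such regardless of the other markers), then IDH-mutant rules
(codeleted ⇒ oligodendroglioma; otherwise astrocytoma, with CDKN2A/B
homozygous deletion as the grade-4 marker), then the IDH-wildtype
glioblastoma rule (TERT promoter mutation, EGFR amplification, or
+7/−10), else not-classifiable with a caveat listing what was missing or
negative. The precedence is this package's ordering of the WHO-CNS5
logic — the source rules do not state one — and is deliberately not a
runtime option. ATRX loss is supportive (recorded in the rule trace for
astrocytoma, caveated when co-occurring with codeletion) rather than
required, since requiring it would misclassify ATRX-intact astrocytomas.
Atypical combinations, such as the rare 1p/19q-codeleted IDH-wildtype
glioblastoma, produce caveats, never errors: the data are what they are.

Actionability: an alteration qualifies when it is a CNA in a mapped gene
or a pathogenic / likely-pathogenic mutation, where likely-pathogenic
means tier-annotated or a hotspot at VAF $\ge$ 15% — the VAF floor keeps
subclonal hotspot calls visible in the report without flagging the
patient actionable on their basis. The gene→trial mapping ships as an
editable TSV.

## Concordance statistics

Cohen's $\kappa$ uses the standard 2×2 formulation
($p_o = (a+d)/N$, $p_e = [(a+b)(a+c) + (c+d)(b+d)]/N^2$), with bands
weak/moderate/strong at 0.4 and 0.8. Sensitivity and specificity are
computed in both reference directions — with sequencing as reference the
counts score conventional testing ($TP=a$, $FN=c$, $TN=d$, $FP=b$), and
vice versa — reported as percentages to two decimals, half-up. Zero
denominators yield not-computable (NA), never 0 or 100. For a 2×2 table
$p_e = 1$ forces $p_o = 1$, so the degenerate single-class case yields
$\kappa = 1$ and the undefined case cannot occur (the guard remains in
code). $\kappa$ is reported at full precision; displays round to three
decimals. The bundled validation counts reproduce their published
statistics to within one unit of the printed precision, with one
three-thousandths-scale rounding artifact in the original presentation
of the TP53 cell, asserted at $|\Delta| \le 0.005$ and not special-cased
in code.

## The synthetic-data generators

The generators produce read-count-level inputs with known truth, seeded
and deterministic:

* **SNP counts**: germline heterozygosity per SNP with probability 0.5
  (the panel's SNPs are selected to be highly polymorphic), per-SNP
  random phase, binomial counts at fixed depth, base-miscall rate 0.001
  so homozygous BAFs are near but not exactly 0/1.
* **Coverage**: expected relative coverage
  $(a\,\mathrm{CN} + (1-a)\cdot 2)/2$ per amplicon with multiplicative
  log-normal noise (default $\sigma = 0.15$ in log2 units, i.e.
  MAPD $\approx 0.14$, a comfortably passing sample; 0.1 for baseline
  normals).
* **Bisulfite counts**: retained-C binomial with success probability
  $m + (1-m)(1-e)$ at conversion efficiency $e$ (default 0.99); non-CpG
  cytosines convert at $e$.
* **FISH tallies**: multinomial over signal patterns with the remainder
  diploid.
* **Cohorts**: the 60-sample diagnostic mix (44 glioblastoma, 5
  astrocytoma, 5 oligodendroglioma, 4 ganglioglioma, 1 gliosarcoma, 1
  midline glioma) with purity uniform on [0.4, 0.9], chosen to span the
  range where all callers are expected to work.

They deliberately do **not** model PCR duplicates, primer-pool imbalance,
GC bias, FFPE deamination artifacts, subclonal heterogeneity, or
sequencer-specific error profiles. Passing tests on this synthetic data
therefore establishes that the decision rules are implemented correctly
and that the callers recover truth under idealized count noise at
realistic purity and depth — not that the thresholds are optimal for any
particular instrument or fixation protocol.

## Problem sizes and numerical choices

The test and acceptance simulations use 200 replicates per condition,
depth 500, 45 SNPs per arm and the full ~2400-amplicon synthetic panel —
large enough that the Monte-Carlo error on a 95% recovery bound is a few
tenths of a percent, small enough to run in seconds. Baseline dispersion
is floored at $10^{-3}$ log2 units (identical normals would otherwise
give zero variance and infinite confidence); p-values are floored at
$10^{-300}$ before $-10\log_{10}$; fractions reported in arm calls are
rounded to three decimals, percentages to two, half away from zero.

## Known limitations

Tumor-only LOH cannot distinguish copy-neutral LOH from deletion without
coverage; segmentation (CBS/HMM) and subclonal fraction estimation are
out of scope, as are germline/somatic deconvolution, bisulfite read
alignment, and image-level FISH analysis. The confidence score is an open
re-specification of a proprietary metric: its gate semantics match, its
values need not. The heterozygosity window asymmetry and the FISH ratio
interaction discussed above are faithful to the source rules, not
endorsements of them.
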