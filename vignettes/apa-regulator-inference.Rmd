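---
title: "Inferring RBP regulators of alternative polyadenylation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring RBP regulators of alternative polyadenylation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apaRegulon)
```

# Scope

`apaRegulon` implements an inference chain for identifying RNA-binding
proteins (RBPs) that regulate alternative polyadenylation (APA) in tandem
terminal exons, by combining three data modalities: a tumor cohort with
per-sample poly(A)-site (PAS) read counts and RBP expression, a panel of
RBP-depletion experiments with replicated control/depleted arms, and CLIP
binding evidence. It also relates APA patterns to tumor purity and
progression-free survival. The package consumes a PAS-level count matrix
(e.g. produced by a coverage-based quantifier from RNA-seq alignments);
alignment, coverage segmentation, and annotation assembly are outside its
scope.

# Usage quantification

## PAU and the binomial usage score

For the PAS of one terminal exon with counts $M_i$ and exon total
$N=\sum_i M_i$, the polyadenylation usage is $PAU_i = M_i/N$ (undefined on
zero-coverage exons). Raw PAU is noisy at low counts, so each site also
receives a signed score from two one-sided binomial tail tests against
$\mathrm{Bin}(N, 1/2)$:

$$\mathrm{score} = -\log_{10} P(m > M) + \log_{10} P(m < M).$$

Both inequalities are strict; the point mass at $M$ belongs to neither
tail. The score is $0$ for a perfectly balanced site, tends to $+\infty$
as the site dominates its exon and to $-\infty$ as it vanishes, and
shrinks toward $0$ at low coverage — which is the point: it discounts
usage estimates that rest on few reads. Tail probabilities are clamped at
the smallest positive normal double so scores stay finite for the PCA and
rank procedures downstream. Both tails are evaluated through the lower
CDF using the $p = 1/2$ symmetry, which makes the antisymmetry
$\mathrm{score}(N-M,N) = -\mathrm{score}(M,N)$ exact in floating point.

## Size factors and library-size control

Size factors follow the median-of-ratios recipe: each count-matrix row is
divided by its row median (rows without a positive median are excluded),
and the size factor of a sample is the median of its column of ratios.

Score magnitudes still grow with sequencing depth. Per PAS, a median
(τ = 0.5) regression of $|\mathrm{score}|$ on library size is fitted
across samples (with an intercept; quantile level and intercept are
conventional defaults). Positive residuals become the normalized score
magnitudes, negative residuals are zeroed, and the original sign is
restored. A PAS needs at least 8 samples with defined scores for the fit;
below that its normalized scores are set to missing, since a median
regression on fewer points is dominated by single observations. A
degenerate fit (constant $|\mathrm{score}|$) yields a flat line and
all-zero normalized scores.

# Differential APA

## Cohort test

Per proximal PAS, with size-factor-normalized counts $r_{PAS}$ (reads
supporting the site) and $r_{other}$ (reads supporting the exon's other
sites), the cohort-level test fits the no-intercept median regression

$$r_{PAS} = \beta_0\, r_{other} + \beta_1 D\, r_{other},$$

where $D$ is the condition indicator. Two-sided t-tests on both
coefficients are combined by their maximum — significance requires both a
dependence on host-exon expression ($\beta_0$) and on condition
($\beta_1$) — and BH-corrected across PAS. Median regression is used
because mean-based count models are anticonservative in large,
heterogeneous human cohorts. Coefficient p-values use the standard
sparsity-based (kernel density, "nid") covariance estimate; when an exact
fit defeats the sparsity estimate, a coefficient is called significant
iff it is numerically nonzero. Condition-wise median PAU and their
difference follow from the coefficients:

$$PAU_0 = \frac{\hat\beta_0}{1+\hat\beta_0},\qquad
  PAU_1 = \frac{\hat\beta_0+\hat\beta_1}{1+\hat\beta_0+\hat\beta_1},\qquad
  \Delta PAU = PAU_1 - PAU_0.$$

Fits with $\hat\beta_0 < 0$ or $\hat\beta_0+\hat\beta_1 < 0$ are flagged
invalid rather than dropped. Results keep the raw `delta_pau` (the
algebraic identity above holds to machine precision) and a sign-adjusted
`delta_pau_signed` (below) separately.

## Shortening versus lengthening

Per exon and sample, PAS positions — strand-aware ranks in transcript
5'→3' orientation, so the convention is identical on both strands — are
averaged with the sample's PAU values as weights. The condition whose
median weighted rank is smaller uses more upstream sites, i.e. has
shorter terminal exons. `delta_pau_signed` is set so that a positive
value for a proximal PAS always means terminal-exon shortening. Ranks
rather than genomic coordinates are used as positions, which makes the
adjustment invariant to the spacing of sites; exons with a single PAS get
direction `none`.

## Depletion experiments

Each depletion experiment (≥2 control and ≥2 depleted replicates) is
tested per proximal PAS on replicate-level counts with a binomial GLM on
the arm indicator. With 2–3 replicates per arm, a per-site dispersion
estimate has so few residual degrees of freedom that even a shift of
several logits cannot reach small p-values, while ignoring dispersion
entirely is badly anticonservative for overdispersed biological
replicates. The default therefore moderates: the per-site Pearson
dispersion is shrunk toward the experiment-wide mean with `prior_df = 10`
prior degrees of freedom (floored at the binomial dispersion of 1), and
the arm coefficient is t-tested at the moderated dispersion with
correspondingly increased degrees of freedom — the same
dispersion-sharing idea used by established per-exon differential-usage
models. The tester is pluggable: `pooled_chisq_tester` (pooled 2×2
chi-square/Fisher) and `quasibinomial_tester` (per-site quasi-binomial)
are provided for comparison, and a model-based caller can be dropped in.
ΔPAU is computed from pooled per-arm counts and BH correction is applied
within each experiment.

Per RBP, significant proximal PAS are rolled up to terminal exons (each
exon votes once, by the sign of the summed sign-adjusted ΔPAU of its
significant sites), and a two-sided binomial test of shortening versus
shortening+lengthening exons at $p = 1/2$, BH-corrected across
experiments and flagged at FDR < 10%, identifies RBPs with a dominant
effect direction. Effect vectors of the same RBP in two cell lines are
compared by cosine similarity over shared tested sites (undefined below 3
shared sites or for all-zero vectors).

# Evidence integration

Every (proximal PAS, RBP) pair testable in the cohort is classified by:

* **CLIP** — the RBP has a binding footprint on the site's host exon;
* **PERT** — the site responds to depletion of the RBP (BH q < 0.05 in
  any retained experiment; the direction is taken from the most
  significant one; significance in a single cell line suffices);
* **CO** — across all retained panel experiments, the site's
  differential-usage status (up/down/nonsig) is dependent on the RBP's
  differential-expression status, by a chi-square test of independence on
  the 3×3 contingency table (empty levels collapsed; tables below 2×2
  untested), at FDR < 0.05. Both margins are trichotomized for symmetry;
* **significant** — the cohort association (two-sided Mann-Whitney test
  of normalized scores between the low- and high-expression halves of the
  cohort, median split by default with ties broken by sample id, tertile
  split available, BH over all pairs) has q < 0.05;
* **consistent** — the pair has PERT evidence and the depletion direction
  equals the low-minus-high cohort direction. Depletion is read as the
  low-expression extreme of the cohort, which is why these two signs —
  and not their opposites — must agree.

The category string is the exact set of {CLIP, PERT, CO} flags, or
`OTHER` when no experimental evidence exists. Differential expression
within an experiment uses a transparent pluggable caller
(median-of-ratios normalization, equal-variance t-test on log2 counts
with pseudocount 0.5, gates q < 0.05 **and** |LFC| > 1); experiments in
which the target RBP itself does not come out "down" fail a depletion
sanity gate and are excluded from the panel.

# Survival and purity

Feature sets for sample-relationship analysis are: top-n genes by median
expression, top-n proximal PAS by fewest zero scores, or a combined set
(⌊n/2⌋ sites + ⌈n/2⌉ genes); ties at any cutoff break lexicographically
by feature id. PCA is centered and unscaled by default (scores and
expression values arrive on comparable, already-normalized scales;
standardization is available via an argument), with each component's sign
fixed so its largest-magnitude loading is positive. Kendall's tau-b with
a seeded percentile bootstrap (default 1000 resamples) measures the
association of component coordinates with tumor purity.

The survival scan transforms a feature to ascending ranks (ties broken by
sample id, so ranks are a permutation of 1..n and the scan is invariant
to monotone transforms) and tests every threshold
$t \in [m, n-m]$ (default minimum group size $m = 30$) with a two-sample
log-rank test; a threshold leaving a group without events records p = 1
with a flag. For a 122-sample cohort this scans exactly ranks 30–92.
The two-axis stratification crosses purity and a component coordinate at
thresholds chosen by each axis's scan argmin (or supplied), yielding up
to four groups compared by a K-sample log-rank test; empty groups are
dropped, so degenerate axes collapse cleanly to the two-sample case.

# The synthetic-data generator

The generator produces the study's data structures with planted ground
truth so that every stage is testable without downloads. Defaults emulate
a mid-sized tumor cohort and a depletion panel:

* 200 terminal exons with 2 tandem PAS (3 supported), negative-binomial
  exon totals (mean 200 reads, dispersion 0.15) scaled by log-normal
  library-size factors (sdlog 0.25);
* within-exon proportions are logistic-normal: proximal log-odds =
  per-site baseline (SD 0.5) + regulator effect + latent APA axis
  (loading 0.25) + per-sample noise (SD 0.3). The logistic-normal choice
  makes regulator effects additive on the logit scale, matching what the
  differential test is built to detect;
* 20 RBPs, 20 planted regulations on distinct proximal sites. A
  regulated site's log-odds shift by `effect_size_logit` (default 1.5)
  per unit z-score of its regulator; regulated RBPs differ between the
  two cohort conditions by one z-score unit, so the planted
  condition-level shift is 1.5 logits on 10% of proximal sites, in a
  cohort of 60 + 60 samples. RBP expression is log-normal in the same
  z-scores, tying the cohort split to the latent regulator state;
* the latent APA axis is sampled independently of condition and then
  centered within each condition: it is defined as a
  condition-independent source of coordinated usage variation (the
  survival-relevant axis), and without centering a finite-sample
  correlation with the condition labels would leak a spurious
  condition-level shift into every site;
* the depletion panel runs one experiment per RBP with 3 + 3 replicates:
  the target's expression is multiplied by 0.25 and its regulator z-score
  drops by 2, so regulated sites shift by 3 logits in the planted
  direction;
* CLIP evidence reports each true (RBP, host exon) pair with probability
  1 − fnr (default fnr 0.2) and each false pair with probability fpr
  (default 0.05);
* survival is exponential with hazard
  $h_0 \exp(\gamma\,\mathrm{purity} + \delta\,f)$ where $f$ is the latent
  APA axis ($h_0 = 0.02$, $\gamma = -2$, $\delta = 1$; purity ~
  Beta(6, 3)), with independent exponential censoring. Only proportional
  hazards matter for the rank-based log-rank procedures, so the simplest
  such model is used;
* one global seed; all sub-generators derive child seeds deterministically
  (a fixed linear-congruential step kept inside the 32-bit integer
  range), so runs are bit-reproducible.

What the generator does *not* emulate: GC or positional coverage bias,
read-level errors, splicing, correlated regulator programs, or the
heavy-tailed library-size and purity distributions of real cohorts.
Passing tests therefore demonstrate the statistical machinery is correct
and calibrated under the stated model, not that real tumor data meet its
assumptions.

# Numerical choices and degenerate inputs

* Binomial tails clamped at the smallest positive normal double; scores
  stay finite.
* Exact quantile-regression fits (zero residual spread) defeat the
  sparsity-based standard error; coefficients are then called by
  numerical nonzeroness (threshold 1e-8).
* Zero-coverage exons give undefined PAU/scores; an arm with zero exon
  coverage leaves the site untested with a recorded reason; a condition
  with all-zero `r_other` likewise.
* A 2×2 table with any expected cell < 5 falls back to Fisher's exact
  test; the CO chi-square collapses empty margin levels and reports
  tables below 2×2 as untested.
* Strict inequalities throughout the QC rules: a replicate pair sitting
  exactly at q75 + 1.5·IQR, or a PAS exactly at the dispersion cutoff, is
  retained. The "strong fluctuation" cutoff, which no reference defines
  quantitatively, defaults to the 90th percentile of per-PAS maximal
  group IQRs and is configurable.
* Outlier filtering embeds with centered PCA by default; the embedding is
  a function argument, so alternative representations can be filtered
  and their flagged pairs unioned.

# Problem sizes used in validation

The test suite and the acceptance script exercise: the full score grid
0 ≤ M ≤ N ≤ 64 against a pmf-summation oracle; 10⁴ random coefficient
pairs for the ΔPAU identity; 25–50 null cohorts of 200 proximal sites at
30 + 30 samples for error control; 10–20 cohorts at the default planted
configuration for power; 5–10 full pipeline runs (cohort + 20-experiment
panel + CLIP) for end-to-end regulator recovery; 122-sample survival
scans (ranks 30–92) plus 200-sample planted-split localization over 30
seeds. These sizes keep a complete run in a few minutes while leaving
every estimate's Monte-Carlo error well inside the margins being tested.

# Known limitations

* The moderated perturbation tester is a stand-in with a fixed prior
  (prior_df = 10), not a fitted dispersion trend; a model-based caller
  can be plugged in where available.
* The cohort split is marginal per RBP; confounding between co-expressed
  RBPs is not modeled, which is precisely why the evidence classification
  intersects the cohort association with perturbation-specific evidence.
* Median regression p-values rely on asymptotic sparsity estimates;
  below ~20 samples per condition they are conservative.
* CLIP evidence is exon-level, so it cannot distinguish between multiple
  proximal sites of the same exon.
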