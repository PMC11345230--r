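# apaRegulon

Tumor transcriptomes show systematic shortening and lengthening of
terminal exons through alternative polyadenylation (APA), but which
RNA-binding proteins (RBPs) drive which poly(A)-site (PAS) choices in a
given cancer is mostly unknown. `apaRegulon` implements an inference
chain that answers this from three data modalities: a tumor cohort
(PAS-level read counts plus RBP expression), a panel of RBP-depletion
experiments, and CLIP binding evidence — and relates the resulting APA
patterns to tumor purity and progression-free survival. It is aimed at
computational biologists who already have a PAS count matrix (from a
coverage-based quantifier) and want regulator calls with explicit,
multi-evidence support.

## The core models

**Usage score.** For a PAS supported by `M` of its exon's `N` reads, two
binomial tail tests against Bin(N, ½) give a signed, coverage-aware usage
score

```
score = -log10 P(m > M) + log10 P(m < M)
```

(0 for a balanced site, +Inf/-Inf limits for dominant/vanishing sites,
shrunk toward 0 at low coverage). Score magnitudes are controlled for
library size by a per-site median regression of |score| on library size;
positive residuals, with the original sign restored, are the normalized
scores.

**Cohort differential APA.** Per proximal PAS, with size-factor-normalized
counts, the no-intercept median regression

```
r_PAS = b0 * r_other + b1 * D * r_other      (D = condition indicator)
```

is fitted; the maximum of the two coefficient t-test p-values is
BH-corrected. Condition-wise usage follows from the fit:
`PAU0 = b0/(1+b0)`, `PAU1 = (b0+b1)/(1+b0+b1)`, `dPAU = PAU1 - PAU0`,
sign-adjusted so that positive proximal dPAU always means terminal-exon
shortening.

**Evidence classification.** Every (proximal PAS, RBP) pair is flagged
CLIP (binding on the host exon), PERT (responds to that RBP's depletion),
CO (panel-wide contingency between usage status and RBP
differential-expression status), significant (cohort Mann-Whitney
association, BH q < 0.05) and consistent (depletion direction equals the
low-minus-high cohort direction). Pairs in PERT ∩ significant ∩
consistent are the regulator calls.

**Survival.** Rank-threshold log-rank scans and a two-axis four-group
stratification relate principal components of usage scores (and tumor
purity) to progression-free survival; Kendall tau with bootstrap CIs
quantifies purity association.

A synthetic-data generator with planted regulations, CLIP error rates,
purity and survival effects makes the whole chain testable end to end;
see the methods vignette (`vignettes/apa-regulator-inference.Rmd`) for
models, defaults and design rationale.

## Worked example

Simulate a 120-sample cohort (20 planted regulations among 200 proximal
sites), a 20-RBP depletion panel and CLIP evidence, then run the chain:

```r
library(apaRegulon)
cfg <- simulation_config(seed = 42)
sim <- simulate_cohort(cfg)

ann    <- sim$counts$annotations
scores <- pas_score_matrix(sim$counts$counts, ann$exon_id)
norm   <- normalize_scores(scores, sim$counts$library_size)

dapa <- dapa_cohort(sim$counts, sim$condition)
pau  <- compute_pau_matrix(sim$counts$counts, ann$exon_id)
dapa <- adjust_direction(dapa, ann, pau, sim$condition)
hits <- dapa[!is.na(dapa$q) & dapa$q < 0.05, ]
head(hits[order(hits$q), c("pas_id", "beta0", "beta1", "q", "pau0",
                           "pau1", "delta_pau", "direction")], 5)
#>          pas_id beta0  beta1        q  pau0  pau1 delta_pau   direction
#> 194 exon0194_p1 0.404  1.026 1.51e-05 0.288 0.589     0.301  shortening
#> 143 exon0143_p1 0.923 -0.688 1.71e-05 0.480 0.190    -0.290 lengthening
#> 18  exon0018_p1 0.146  0.625 3.47e-05 0.128 0.435     0.308  shortening
#> 22  exon0022_p1 1.902 -1.338 3.47e-05 0.655 0.361    -0.295 lengthening
#> 55  exon0055_p1 1.411 -1.074 3.47e-05 0.585 0.252    -0.333 lengthening
```

18 sites reach q < 0.05; 17 of them carry a planted regulation. Each row
reads: site `exon0194_p1` is used more in condition 1 (PAU 0.29 → 0.59),
and since it is proximal that shift shortens its terminal exon.

```r
panel  <- simulate_perturbation_panel(cfg, sim$truth)
clip   <- simulate_clip(sim$truth, clip_fpr = 0.05, clip_fnr = 0.2, seed = 42)
pres   <- dapa_panel(panel$counts, panel$design)
de     <- de_status_matrix(panel$expr, panel$design)
prox   <- ann$pas_id[!ann$is_distal]
cohort <- cohort_association(norm$normalized_score[prox, ], sim$rbp_expr)
co     <- co_tests(dapa_status_matrix(pres), de$status)
recs   <- classify_pairs(cohort, pres, panel$design, clip, co, ann)
category_summary(recs)
#>       category    n n_significant n_consistent
#> 1         CLIP  186             9            0
#> 2 CLIP+PERT+CO   15            15           13
#> 3        OTHER 3795           216            0
#> 4      PERT+CO    4             4            4
```

Experimental evidence concentrates the cohort-significant pairs: all 19
PERT-evidenced pairs are significant, versus 216 of 3795 `OTHER` pairs.
The PERT ∩ significant ∩ consistent set contains 17 pairs, all planted
(precision 1.00, recall 0.85 of the 20 planted regulations).

```r
feat <- select_features(log2(sim$rbp_expr), norm$normalized_score[prox, ],
                        "apa", 150)
pc   <- pca_embed(feat)
scan <- logrank_scan(pc$coordinates[, 2], sim$clinical$time,
                     sim$clinical$event, min_group = 30)
c(best = scan$best_threshold, min_p = min(scan$p))
#> scan thresholds 30..90, best threshold 82, min p 3.95e-06
```

The scan over usage-score PC2 finds a rank split strongly associated with
progression-free survival — the generator plants a latent APA axis in the
hazard, and the scan recovers it.

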