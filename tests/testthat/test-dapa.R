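test_that("noiseless proportional counts are fitted exactly", {
  fx <- exact_fit_pcm(b0 = 1, b1 = 0)
  res <- dapa_cohort(fx$pcm, fx$cond, sf = fx$sf)
  expect_equal(res$beta0, 1, tolerance = 1e-6)
  expect_equal(res$beta1, 0, tolerance = 1e-6)
  expect_equal(res$pau0, 0.5, tolerance = 1e-6)
  expect_equal(res$pau1, 0.5, tolerance = 1e-6)
  expect_equal(res$delta_pau, 0, tolerance = 1e-6)

  fx2 <- exact_fit_pcm(b0 = 1, b1 = 1)
  res2 <- dapa_cohort(fx2$pcm, fx2$cond, sf = fx2$sf)
  expect_equal(res2$beta0, 1, tolerance = 1e-6)
  expect_equal(res2$beta1, 1, tolerance = 1e-6)
  expect_equal(res2$pau0, 1 / 2, tolerance = 1e-6)
  expect_equal(res2$pau1, 2 / 3, tolerance = 1e-6)
  expect_equal(res2$delta_pau, 1 / 6, tolerance = 1e-6)
  # a clear condition effect on noiseless data is maximally significant
  expect_lt(res2$p_max, 1e-6)
})

test_that("delta PAU equals the difference of the fitted-PAU formulas", {
  set.seed(2)
  b0 <- stats::rexp(1e4); b1 <- stats::rexp(1e4) - b0 * stats::runif(1e4)
  b1 <- pmax(b1, -b0)                       # keep beta0 + beta1 >= 0
  pp <- pau_from_beta(b0, b1)
  expect_equal(pp$delta_pau,
               (b0 + b1) / (1 + b0 + b1) - b0 / (1 + b0), tolerance = 1e-12)
  expect_true(all(pp$pau0 >= 0 & pp$pau0 <= 1))
  expect_true(all(pp$pau1 >= 0 & pp$pau1 <= 1))
})

test_that("swapping condition labels flips beta1 and delta PAU", {
  cfg <- simulation_config(n_exons = 40, n_samples_per_condition = 20, seed = 12)
  sim <- simulate_cohort(cfg)
  sf <- size_factors(sim$counts$counts)
  a <- dapa_cohort(sim$counts, sim$condition, sf)
  b <- dapa_cohort(sim$counts, 1 - sim$condition, sf)
  ok <- is.na(a$reason) & is.na(b$reason)
  # reparametrization: beta0' = beta0 + beta1, beta1' = -beta1
  expect_equal(b$beta1[ok], -a$beta1[ok], tolerance = 1e-6)
  expect_equal(b$beta0[ok], a$beta0[ok] + a$beta1[ok], tolerance = 1e-6)
  v <- ok & a$valid & b$valid
  expect_equal(b$delta_pau[v], -a$delta_pau[v], tolerance = 1e-6)
})

test_that("null cohorts keep the q < 0.05 call rate controlled", {
  cfg <- simulation_config(n_exons = 100, n_true_regulations = 0,
                           n_samples_per_condition = 30, seed = 31)
  sim <- simulate_cohort(cfg)
  res <- dapa_cohort(sim$counts, sim$condition)
  expect_lte(mean(res$q < 0.05, na.rm = TRUE), 0.05)
})

test_that("weighted-rank direction calls shortening and lengthening correctly", {
  ann <- two_site_exon("+")
  # condition 1 (cols 3,4) uses the proximal site more
  pau <- matrix(c(0.2, 0.8, 0.2, 0.8, 0.7, 0.3, 0.7, 0.3), 2,
                dimnames = list(c("p1", "p2"), NULL))
  res <- data.frame(pas_id = "p1", exon_id = "exonA", delta_pau = 0.5,
                    stringsAsFactors = FALSE)
  out <- adjust_direction(res, ann, pau, c(0, 0, 1, 1))
  expect_equal(out$direction, "shortening")
  expect_gt(out$delta_pau_signed, 0)

  # minus-strand mirror of the same usage pattern: identical call
  ann_m <- two_site_exon("-")
  pau_m <- pau[c("p2", "p1"), ]             # p2 is proximal on minus strand
  rownames(pau_m) <- c("p1", "p2")
  pau_m <- pau_m[match(ann_m$pas_id, rownames(pau_m)), ]
  out_m <- adjust_direction(
    data.frame(pas_id = ann_m$pas_id[!ann_m$is_distal], exon_id = "exonA",
               delta_pau = 0.5, stringsAsFactors = FALSE),
    ann_m, pau_m, c(0, 0, 1, 1))
  expect_equal(out_m$direction, "shortening")

  # three sites: usage moving from the middle to the distal site lengthens
  ann3 <- assign_pas_ranks(data.frame(
    pas_id = c("a", "b", "c"), exon_id = "e3", gene_id = "g", chrom = "chr1",
    start = c(10, 20, 30), end = c(11, 21, 31), strand = "+",
    stringsAsFactors = FALSE))
  pau3 <- cbind(c(0.2, 0.6, 0.2), c(0.2, 0.6, 0.2),
                c(0.2, 0.1, 0.7), c(0.2, 0.1, 0.7))
  rownames(pau3) <- c("a", "b", "c")
  res3 <- data.frame(pas_id = "b", exon_id = "e3", delta_pau = -0.5,
                     stringsAsFactors = FALSE)
  out3 <- adjust_direction(res3, ann3, pau3, c(0, 0, 1, 1))
  expect_equal(out3$direction, "lengthening")
  expect_lt(out3$delta_pau_signed, 0)

  # single-PAS exon has no direction
  ann1 <- assign_pas_ranks(data.frame(
    pas_id = "solo", exon_id = "e1", gene_id = "g", chrom = "chr1",
    start = 1, end = 2, strand = "+", stringsAsFactors = FALSE))
  out1 <- adjust_direction(
    data.frame(pas_id = "solo", exon_id = "e1", delta_pau = 0.1,
               stringsAsFactors = FALSE),
    ann1, matrix(1, 1, 4, dimnames = list("solo", NULL)), c(0, 0, 1, 1))
  expect_equal(out1$direction, "none")
})

test_that("perturbation test handles equal proportions and planted shifts", {
  ann <- two_site_exon("+")
  design <- data.frame(experiment_id = "x1", cell_line = "K562",
                       target_rbp = "R1",
                       sample_id = c("c1", "c2", "k1", "k2"),
                       arm = rep(c("control", "depleted"), each = 2),
                       replicate = c(1, 2, 1, 2), stringsAsFactors = FALSE)
  # identical pooled proportions in both arms
  counts_eq <- matrix(c(50, 50, 40, 40, 50, 50, 40, 40), 2, byrow = TRUE,
                      dimnames = list(c("p1", "p2"),
                                      c("c1", "c2", "k1", "k2")))
  res <- dapa_perturbation(pas_count_matrix(counts_eq, ann), design)
  expect_equal(res$delta_pau, 0)
  expect_equal(res$p, 1)

  # strong planted proximal-up shift at depth
  counts_up <- matrix(c(100, 100, 500, 500, 400, 400, 100, 100), 2,
                      byrow = TRUE,
                      dimnames = list(c("p1", "p2"),
                                      c("c1", "c2", "k1", "k2")))
  res_up <- dapa_perturbation(pas_count_matrix(counts_up, ann), design)
  expect_gt(res_up$delta_pau, 0)
  expect_lt(res_up$q, 0.05)
  expect_equal(res_up$direction, "shortening")

  expect_error(dapa_perturbation(pas_count_matrix(counts_eq, ann),
                                 design[c(1, 3, 4), ]), ">= 2 replicates")
})

test_that("the pooled chi-square tester matches the closed form", {
  # table [[10, 0], [0, 10]]: uncorrected chi-square statistic is 20
  p <- pooled_chisq_tester(m_ctl = 10, o_ctl = 0, m_kd = 0, o_kd = 10,
                           correct = FALSE)
  expect_equal(p, stats::pchisq(20, 1, lower.tail = FALSE), tolerance = 1e-12)
  # sparse tables fall back to the exact test
  p2 <- pooled_chisq_tester(m_ctl = 3, o_ctl = 1, m_kd = 1, o_kd = 3)
  expect_equal(p2, stats::fisher.test(rbind(c(3, 1), c(1, 3)))$p.value)
})

test_that("per-RBP summaries count exons and test direction balance", {
  design <- data.frame(experiment_id = c("x1", "x2", "x3"),
                       cell_line = "K562",
                       target_rbp = c("R1", "R2", "R3"),
                       sample_id = c("a", "b", "c"), arm = "control",
                       replicate = 1, stringsAsFactors = FALSE)
  panel <- list(
    x1 = fake_dapa_result(c(rep(1, 8), rep(-1, 2))),   # 8 short, 2 long
    x2 = fake_dapa_result(c(rep(1, 5), rep(-1, 5))),   # balanced
    x3 = fake_dapa_result(numeric(0)))                 # nothing significant
  out <- rbp_effect_summary(panel, design)
  s <- out$summary
  expect_equal(s$n_shortening[s$experiment_id == "x1"], 8)
  expect_equal(s$log2_ratio[s$experiment_id == "x1"], 2)
  expect_equal(s$p_binomial[s$experiment_id == "x1"], 112 / 1024,
               tolerance = 1e-12)
  expect_equal(s$log2_ratio[s$experiment_id == "x2"], 0)
  expect_equal(s$p_binomial[s$experiment_id == "x2"], 1)
  expect_equal(s$n_significant[s$experiment_id == "x3"], 0)
  expect_true(is.na(s$p_binomial[s$experiment_id == "x3"]))
  expect_false(s$fdr_flag[s$experiment_id == "x3"])
})

test_that("cross-cell-line cosine similarity behaves on canonical vectors", {
  mk <- function(v, exp_id, rbp) {
    eff <- stats::setNames(v, sprintf("p%d", seq_along(v)))
    list(summary = data.frame(experiment_id = exp_id, rbp_id = rbp,
                              stringsAsFactors = FALSE),
         effects = stats::setNames(list(eff), exp_id))
  }
  v <- c(0.3, -0.2, 0.5, 0.1)
  expect_equal(cross_cellline_consistency(mk(v, "a", "R"),
                                          mk(v, "b", "R"))$cosine, 1)
  expect_equal(cross_cellline_consistency(mk(v, "a", "R"),
                                          mk(-v, "b", "R"))$cosine, -1)
  expect_equal(cross_cellline_consistency(mk(c(1, 0, 0), "a", "R"),
                                          mk(c(0, 1, 0), "b", "R"))$cosine, 0)
  few <- cross_cellline_consistency(mk(v[1:2], "a", "R"), mk(v[1:2], "b", "R"))
  expect_true(is.na(few$cosine))
  expect_match(few$reason, "fewer than 3")
  zero <- cross_cellline_consistency(mk(c(0, 0, 0), "a", "R"),
                                     mk(c(1, 1, 1), "b", "R"))
  expect_match(zero$reason, "all-zero")
})

test_that("cohort and perturbation tests agree in direction on shared effects", {
  cfg <- simulation_config(n_exons = 80, n_true_regulations = 16, seed = 17)
  sim <- simulate_cohort(cfg)
  panel <- simulate_perturbation_panel(cfg, sim$truth)
  coh <- dapa_cohort(sim$counts, sim$condition)
  pres <- dapa_panel(panel$counts, panel$design)
  reg <- sim$truth$regulations
  agree <- c()
  for (i in seq_len(nrow(reg))) {
    crow <- coh[coh$pas_id == reg$pas_id[i], ]
    exps <- unique(panel$design$experiment_id[panel$design$target_rbp == reg$rbp_id[i]])
    prow <- pres[[exps[1]]]
    prow <- prow[prow$pas_id == reg$pas_id[i], ]
    if (!is.na(crow$q) && crow$q < 0.05 && !is.na(prow$q) && prow$q < 0.05) {
      # condition 1 carries the high regulator state and depletion the low
      # extreme, so the two delta PAUs must have opposite signs
      agree <- c(agree, sign(prow$delta_pau) == -sign(crow$delta_pau))
    }
  }
  expect_gt(length(agree), 5)
  expect_gte(mean(agree), 0.95)
})
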