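test_that("cohort association reproduces the exact rank-sum p-value", {
  # scores 1..3 in the low-expression half vs 4..6 in the high half:
  # complete separation of 3 vs 3 gives exact two-sided p = 2/20 = 0.1
  sc <- matrix(1:6, 1, dimnames = list("pas1", sprintf("s%d", 1:6)))
  expr <- matrix(1:6, 1, dimnames = list("R1", sprintf("s%d", 1:6)))
  out <- cohort_association(sc, expr, min_per_cohort = 3)
  expect_equal(out$p, 0.1)
  expect_equal(out$direction, -1)
  expect_equal(out$median_low, 2)
  expect_equal(out$median_high, 5)

  # constant scores: p = 1, direction 0
  sc0 <- matrix(5, 1, 6, dimnames = list("pas1", sprintf("s%d", 1:6)))
  out0 <- cohort_association(sc0, expr, min_per_cohort = 3)
  expect_equal(out0$p, 1)
  expect_equal(out0$direction, 0)

  expect_error(cohort_association(sc, expr, min_per_cohort = 10),
               "fewer than 10")
})

test_that("a planted regulator pair is recovered by the cohort split", {
  hits <- vapply(1:10, function(s) {
    cfg <- simulation_config(n_exons = 60, n_true_regulations = 6,
                             n_samples_per_condition = 50, seed = s)
    sim <- simulate_cohort(cfg)
    ann <- sim$counts$annotations
    sc <- pas_score_matrix(sim$counts$counts, ann$exon_id)
    ns <- normalize_scores(sc, sim$counts$library_size)
    prox <- ann$pas_id[!ann$is_distal]
    out <- cohort_association(ns$normalized_score[prox, ], sim$rbp_expr)
    reg <- sim$truth$regulations[1, ]
    row <- out[out$pas_id == reg$pas_id & out$rbp_id == reg$rbp_id, ]
    expected_dir <- if (reg$direction == "proximal-up-on-depletion") 1 else -1
    !is.na(row$q) && row$q < 0.05 && row$direction == expected_dir
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("the co-variation chi-square matches the closed form and degenerates", {
  # perfect anti-association over 40 experiments, no nonsig level:
  # the collapsed 2x2 gives chi-square = n = 40
  apa <- rep(c("up", "down"), each = 20)
  de <- rep(c("down", "up"), each = 20)
  ct <- co_test(apa, de)
  expect_equal(ct$chi2, 40, tolerance = 1e-12)
  expect_lt(ct$p, 0.001)

  allnon <- rep("nonsig", 25)
  ct2 <- co_test(allnon, allnon)
  expect_true(is.na(ct2$p))
  expect_match(ct2$reason, "below 2x2")

  expect_error(co_test(apa[1:10], de[1:10]), "at least 20")
})

test_that("independent statuses keep the co-test near nominal level", {
  set.seed(33)
  pv <- replicate(200, {
    a <- sample(c("up", "down", "nonsig"), 60, replace = TRUE)
    d <- sample(c("up", "down", "nonsig"), 60, replace = TRUE)
    co_test(a, d)$p
  })
  expect_lt(mean(pv < 0.05, na.rm = TRUE), 0.12)
})

test_that("the DE caller gates on both significance and fold change", {
  set.seed(5)
  design <- data.frame(experiment_id = "x1", cell_line = "K562",
                       target_rbp = "R1",
                       sample_id = c("c1", "c2", "c3", "k1", "k2", "k3"),
                       arm = rep(c("control", "depleted"), each = 3),
                       replicate = rep(1:3, 2), stringsAsFactors = FALSE)
  base <- matrix(rpois(5 * 6, 1000), 5, 6,
                 dimnames = list(c("R1", "R2", "R3", "R4", "R5"),
                                 design$sample_id))
  expr <- base
  expr["R1", 4:6] <- rpois(3, 250)         # knocked down to one quarter
  out <- de_status(expr, design)
  expect_equal(out$status[out$gene_id == "R1"], "down")
  expect_true(attr(out, "gate_pass"))
  expect_true(all(out$status[out$gene_id != "R1"] == "nonsig"))

  # identical arms: everything nonsig, gate fails
  out2 <- de_status(base, design)
  expect_true(all(out2$status == "nonsig"))
  expect_false(attr(out2, "gate_pass"))

  # large fold change with huge replicate noise stays nonsig (q gate)
  noisy <- base
  noisy["R2", ] <- c(10, 4000, 50, 2000, 1, 300)
  out3 <- de_status(noisy, design)
  expect_equal(out3$status[out3$gene_id == "R2"], "nonsig")
})

test_that("association records assemble evidence flags and categories", {
  ann <- two_site_exon("+")
  cohort <- data.frame(pas_id = c("p1", "p1"), rbp_id = c("R1", "R2"),
                       p = c(0.001, 0.0005), q = c(0.01, 0.001),
                       direction = c(1, 1), median_low = 1, median_high = 0,
                       stringsAsFactors = FALSE)
  design <- data.frame(experiment_id = c("x1", "x2"), cell_line = "K562",
                       target_rbp = c("R1", "R2"), sample_id = c("a", "b"),
                       arm = "control", replicate = 1, stringsAsFactors = FALSE)
  pert_hit <- data.frame(pas_id = "p1", exon_id = "exonA", delta_pau = 0.3,
                         p = 1e-4, q = 1e-3, reason = NA_character_,
                         stringsAsFactors = FALSE)
  pert_null <- transform(pert_hit, p = 0.9, q = 0.9)
  clip <- data.frame(rbp_id = "R1", exon_id = "exonA", stringsAsFactors = FALSE)

  recs <- classify_pairs(cohort, list(x1 = pert_hit, x2 = pert_null),
                         design, clip, co_res = NULL, ann)
  r1 <- recs[recs$rbp_id == "R1", ]
  expect_equal(r1$category, "CLIP+PERT")
  expect_true(r1$significant)
  expect_true(r1$consistent)                # pert dir +1 == cohort dir +1
  r2 <- recs[recs$rbp_id == "R2", ]
  expect_equal(r2$category, "OTHER")
  expect_true(r2$significant)
  expect_false(r2$consistent)

  # every record carries exactly one category; counts add up
  cs <- category_summary(recs)
  expect_equal(sum(cs$n), nrow(recs))

  # flipping the cohort split flips both directions, leaving consistency
  cohort_flip <- transform(cohort, direction = -direction)
  pert_flip <- transform(pert_hit, delta_pau = -delta_pau)
  recs_f <- classify_pairs(cohort_flip, list(x1 = pert_flip, x2 = pert_null),
                           design, clip, co_res = NULL, ann)
  expect_equal(recs_f$consistent[recs_f$rbp_id == "R1"], r1$consistent)
})

test_that("experimental evidence enriches cohort-significant pairs", {
  cfg <- simulation_config(seed = 19)
  sim <- simulate_cohort(cfg)
  panel <- simulate_perturbation_panel(cfg, sim$truth)
  clip <- simulate_clip(sim$truth, 0.05, 0.2, cfg$seed)
  pres <- dapa_panel(panel$counts, panel$design)
  ann <- sim$counts$annotations
  sc <- pas_score_matrix(sim$counts$counts, ann$exon_id)
  ns <- normalize_scores(sc, sim$counts$library_size)
  prox <- ann$pas_id[!ann$is_distal]
  cohort <- cohort_association(ns$normalized_score[prox, ], sim$rbp_expr)
  recs <- classify_pairs(cohort, pres, panel$design, clip, co_res = NULL, ann)
  with_ev <- recs[recs$category != "OTHER", ]
  other <- recs[recs$category == "OTHER", ]
  expect_gt(mean(with_ev$significant), mean(other$significant))
})
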