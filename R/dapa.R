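#' @importFrom stats median p.adjust pchisq
NULL

# coefficient p-values from a median-regression fit, robust to exact fits
rq_coef_pvalues <- function(fit, n) {
  b <- stats::coef(fit)
  s <- tryCatch(suppressWarnings(summary(fit, se = "nid", covariance = TRUE)),
                error = function(e) NULL)
  if (is.null(s))
    s <- tryCatch(suppressWarnings(summary(fit, se = "iid", covariance = TRUE)),
                  error = function(e) NULL)
  p <- if (!is.null(s)) s$coefficients[, 4] else rep(NaN, length(b))
  bad <- !is.finite(p)
  if (any(bad)) {
    # exact or degenerate fit: zero residual spread defeats the sparsity
    # estimate; call a coefficient significant iff it is numerically nonzero
    p[bad] <- ifelse(abs(b[bad]) > 1e-8, 0, 1)
  }
  p
}

#' Cohort-level differential APA test by no-intercept median regression
#'
#' For each proximal PAS, the size-factor-normalized reads supporting the
#' site (`r_pas`) are regressed on the normalized reads supporting the other
#' sites of its exon (`r_other`) with a condition interaction and no
#' intercept: `r_pas = beta0 * r_other + beta1 * D * r_other`, fitted at the
#' median (tau = 0.5).  Two-sided t-tests on both coefficients are combined
#' by their maximum (significance requires both association with host-exon
#' expression and dependence on condition) and BH-adjusted across PAS.
#' Condition-wise median PAU and their difference are recovered from the
#' coefficients: `PAU0 = b0/(1+b0)`, `PAU1 = (b0+b1)/(1+b0+b1)`.
#'
#' @param pcm a [pas_count_matrix()].
#' @param condition vector with two levels over samples; the second level
#'   (factor order) is coded D = 1.
#' @param sf optional size factors; computed by [size_factors()] if NULL.
#' @param min_per_condition minimum samples per condition.
#' @return data.frame with pas_id, exon_id, beta0, beta1, p_beta0, p_beta1,
#'   p_max, q, pau0, pau1, delta_pau, valid (both fitted PAU in range) and
#'   reason (NA when tested).
#' @export
dapa_cohort <- function(pcm, condition, sf = NULL, min_per_condition = 10) {
  stopifnot(inherits(pcm, "pas_count_matrix"))
  cond <- as.integer(factor(condition)) - 1L
  if (length(unique(cond)) != 2) stop("condition must have exactly two levels")
  if (any(table(cond) < min_per_condition))
    stop("need at least ", min_per_condition, " samples per condition")
  if (is.null(sf)) sf <- size_factors(pcm$counts)
  norm <- sweep(pcm$counts, 2, sf, "/")
  ann <- pcm$annotations
  exon_tot <- rowsum(norm, ann$exon_id)[ann$exon_id, , drop = FALSE]
  proximal <- which(!ann$is_distal)

  res <- lapply(proximal, function(i) {
    y <- norm[i, ]
    x <- exon_tot[i, ] - y
    row <- data.frame(pas_id = ann$pas_id[i], exon_id = ann$exon_id[i],
                      beta0 = NA_real_, beta1 = NA_real_,
                      p_beta0 = NA_real_, p_beta1 = NA_real_,
                      p_max = NA_real_, q = NA_real_,
                      pau0 = NA_real_, pau1 = NA_real_, delta_pau = NA_real_,
                      valid = NA, reason = NA_character_,
                      stringsAsFactors = FALSE)
    if (any(tapply(x, cond, function(v) all(v == 0)))) {
      row$reason <- "all-zero r_other in a condition"
      return(row)
    }
    xd <- x * cond
    fit <- tryCatch(
      suppressWarnings(quantreg::rq(y ~ 0 + x + xd, tau = 0.5)),
      error = function(e) NULL)
    if (is.null(fit)) {
      row$reason <- "fit failed"
      return(row)
    }
    b <- stats::coef(fit)
    p <- rq_coef_pvalues(fit, length(y))
    row$beta0 <- unname(b[1]); row$beta1 <- unname(b[2])
    row$p_beta0 <- unname(p[1]); row$p_beta1 <- unname(p[2])
    row$p_max <- max(p)
    row$valid <- b[1] >= 0 && (b[1] + b[2]) >= 0
    pau <- pau_from_beta(b[1], b[2])
    if (row$valid) {
      row$pau0 <- pau$pau0; row$pau1 <- pau$pau1; row$delta_pau <- pau$delta_pau
    }
    row
  })
  out <- do.call(rbind, res)
  tested <- is.na(out$reason)
  out$q[tested] <- stats::p.adjust(out$p_max[tested], "BH")
  rownames(out) <- NULL
  out
}

#' Condition-wise PAU and their difference from fitted coefficients
#'
#' @param beta0,beta1 median-regression coefficients (vectorized).
#' @return list with pau0 = beta0/(1+beta0),
#'   pau1 = (beta0+beta1)/(1+beta0+beta1), delta_pau = pau1 - pau0.
#' @export
pau_from_beta <- function(beta0, beta1) {
  pau0 <- beta0 / (1 + beta0)
  pau1 <- (beta0 + beta1) / (1 + beta0 + beta1)
  list(pau0 = pau0, pau1 = pau1, delta_pau = pau1 - pau0)
}

# per-exon terminal-exon length direction between two groups: the
# PAU-weighted mean PAS rank (transcript orientation) is computed per
# sample; the group with the smaller median weighted rank has shorter TEs
exon_length_direction <- function(pau, ann, group) {
  stopifnot(nrow(pau) == nrow(ann), ncol(pau) == length(group))
  g1 <- group == sort(unique(group))[2]
  dirs <- vapply(split(seq_len(nrow(ann)), ann$exon_id), function(ix) {
    if (length(ix) < 2) return("none")
    w <- pau[ix, , drop = FALSE] * ann$rank_from_5p[ix]
    wrank <- colSums(w)                     # PAU sums to 1 per exon/sample
    d <- stats::median(wrank[g1], na.rm = TRUE) -
         stats::median(wrank[!g1], na.rm = TRUE)
    if (is.na(d) || d == 0) "none" else if (d < 0) "shortening" else "lengthening"
  }, "")
  dirs
}

#' Assign shortening/lengthening direction and sign-adjust delta PAU
#'
#' Per exon and sample, PAS positions (strand-aware ranks) are averaged with
#' the sample's PAU values as weights; the condition whose median weighted
#' rank is smaller has shorter terminal exons.  `delta_pau_signed` is then
#' set so that a positive value for a proximal PAS always means terminal
#' exon shortening (in condition 1 relative to condition 0).
#'
#' @param results data.frame from [dapa_cohort()] or [dapa_perturbation()].
#' @param ann `pas_annotation` data.frame.
#' @param pau PAS x samples PAU matrix aligned with `ann`.
#' @param condition two-level vector over the PAU columns (second level is
#'   condition 1, matching the regression coding).
#' @return `results` with columns `direction` and `delta_pau_signed` added.
#' @export
adjust_direction <- function(results, ann, pau, condition) {
  cond <- as.integer(factor(condition)) - 1L
  dirs <- exon_length_direction(pau, ann, cond)
  results$direction <- unname(dirs[results$exon_id])
  d <- results$delta_pau
  results$delta_pau_signed <- ifelse(
    results$direction == "shortening", abs(d),
    ifelse(results$direction == "lengthening", -abs(d), d))
  results
}

#' Replicate-aware quasi-binomial tester for one proximal PAS
#'
#' Default per-experiment tester: replicate-level counts (reads supporting
#' the PAS versus the exon's other sites) are modeled with a quasi-binomial
#' GLM on the arm indicator, so extra-binomial dispersion between
#' biological replicates widens the test appropriately; the p-value is the
#' two-sided t-test on the arm coefficient.
#'
#' @param m_ctl,o_ctl,m_kd,o_kd per-replicate PAS and other-site counts in
#'   the control and depleted arms.
#' @return two-sided p-value.
#' @export
quasibinomial_tester <- function(m_ctl, o_ctl, m_kd, o_kd) {
  m <- c(m_ctl, m_kd); o <- c(o_ctl, o_kd)
  arm <- rep(c(0, 1), c(length(m_ctl), length(m_kd)))
  keep <- (m + o) > 0
  fit <- suppressWarnings(
    stats::glm(cbind(m, o) ~ arm, family = stats::quasibinomial,
               subset = keep))
  co <- suppressWarnings(summary(fit)$coefficients)
  if (nrow(co) < 2 || !is.finite(co["arm", 4])) return(1)
  co["arm", 4]
}

#' Pooled 2x2 chi-square tester
#'
#' Simple alternative tester: replicate counts are pooled per arm into a
#' 2x2 table (PAS reads vs other-site reads, control vs depleted) and
#' tested by chi-square (continuity-corrected by default; Fisher's exact
#' test when any expected cell is below 5).  Powerful but blind to
#' replicate-level dispersion.
#'
#' @inheritParams quasibinomial_tester
#' @param correct continuity correction for the chi-square test.
#' @return two-sided p-value.
#' @export
pooled_chisq_tester <- function(m_ctl, o_ctl, m_kd, o_kd, correct = TRUE) {
  tab <- rbind(pas = c(sum(m_ctl), sum(m_kd)),
               other = c(sum(o_ctl), sum(o_kd)))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5))
    stats::fisher.test(tab)$p.value
  else
    suppressWarnings(stats::chisq.test(tab, correct = correct)$p.value)
}

#' Per-experiment differential APA test for a depletion experiment
#'
#' Transparent stand-in for a per-exon differential-usage model.  Per
#' proximal PAS, replicate-level counts (reads supporting the PAS versus
#' the exon's other sites, per arm) enter a binomial GLM on the arm
#' indicator; extra-binomial dispersion is estimated per PAS (Pearson) and
#' shrunk toward the experiment-wide mean with `prior_df` prior degrees of
#' freedom, in the spirit of dispersion-sharing differential-usage models
#' — with few replicates a raw per-site dispersion estimate leaves too few
#' degrees of freedom to detect even large shifts.  The p-value is the
#' two-sided t-test on the arm coefficient at the moderated dispersion.
#' Delta PAU is the pooled PAU difference (depleted - control); identical
#' pooled proportions short-circuit to p = 1.  BH correction is applied
#' within the experiment.  Direction and `delta_pau_signed` follow the
#' same weighted-rank rule as the cohort test, computed on pooled per-arm
#' PAU.  A pluggable `tester` (e.g. [quasibinomial_tester()] or
#' [pooled_chisq_tester()]) replaces the moderated default.
#'
#' @param pcm [pas_count_matrix()] restricted to (or containing) the
#'   experiment's samples.
#' @param design design data.frame rows for one experiment (columns
#'   sample_id, arm).
#' @param tester NULL for the moderated default, or a function
#'   `function(m_ctl, o_ctl, m_kd, o_kd) -> p-value`.
#' @param prior_df prior degrees of freedom for dispersion moderation.
#' @return data.frame with pas_id, exon_id, delta_pau, p, q, direction,
#'   delta_pau_signed, reason.
#' @export
dapa_perturbation <- function(pcm, design, tester = NULL, prior_df = 10) {
  stopifnot(inherits(pcm, "pas_count_matrix"))
  design <- design[design$sample_id %in% pcm$samples, , drop = FALSE]
  if (any(table(design$arm) < 2)) stop("need >= 2 replicates per arm")
  ann <- pcm$annotations
  ctl <- design$sample_id[design$arm == "control"]
  kd <- design$sample_id[design$arm == "depleted"]
  pooled <- cbind(control = rowSums(pcm$counts[, ctl, drop = FALSE]),
                  depleted = rowSums(pcm$counts[, kd, drop = FALSE]))
  exon_tot_rep <- rowsum(pcm$counts, ann$exon_id)[ann$exon_id, , drop = FALSE]
  exon_tot <- rowsum(pooled, ann$exon_id)[ann$exon_id, , drop = FALSE]
  proximal <- which(!ann$is_distal)
  res <- lapply(proximal, function(i) {
    row <- data.frame(pas_id = ann$pas_id[i], exon_id = ann$exon_id[i],
                      delta_pau = NA_real_, p = NA_real_, q = NA_real_,
                      coef = NA_real_, se0 = NA_real_, phi = NA_real_,
                      df_resid = NA_real_,
                      reason = NA_character_, stringsAsFactors = FALSE)
    if (any(exon_tot[i, ] == 0)) {
      row$reason <- "zero exon coverage in an arm"
      return(row)
    }
    row$delta_pau <- pooled[i, 2] / exon_tot[i, 2] -
                     pooled[i, 1] / exon_tot[i, 1]
    m_ctl <- pcm$counts[i, ctl]; m_kd <- pcm$counts[i, kd]
    o_ctl <- exon_tot_rep[i, ctl] - m_ctl
    o_kd <- exon_tot_rep[i, kd] - m_kd
    if (!is.null(tester)) {
      row$p <- if (row$delta_pau == 0) 1 else tester(m_ctl, o_ctl, m_kd, o_kd)
      return(row)
    }
    m <- c(m_ctl, m_kd); o <- c(o_ctl, o_kd)
    arm <- rep(c(0, 1), c(length(m_ctl), length(m_kd)))
    keep <- (m + o) > 0
    fit <- suppressWarnings(
      stats::glm(cbind(m, o) ~ arm, family = stats::binomial, subset = keep))
    co <- suppressWarnings(summary(fit)$coefficients)
    if (!("arm" %in% rownames(co))) {
      row$reason <- "degenerate fit"
      return(row)
    }
    row$coef <- co["arm", 1]
    row$se0 <- co["arm", 2]
    row$df_resid <- fit$df.residual
    pear <- sum(stats::residuals(fit, type = "pearson")^2)
    row$phi <- if (fit$df.residual > 0) pear / fit$df.residual else NA_real_
    row
  })
  out <- do.call(rbind, res)

  if (is.null(tester)) {
    # moderated dispersion: shrink per-PAS Pearson dispersion toward the
    # experiment-wide mean; never below 1 (binomial floor)
    est <- !is.na(out$phi) & is.finite(out$phi)
    phi_bar <- if (any(est)) mean(out$phi[est]) else 1
    fit_ok <- !is.na(out$coef)
    d <- ifelse(is.na(out$df_resid), 0, out$df_resid)
    phi_mod <- pmax((d * ifelse(is.na(out$phi), 0, out$phi) +
                     prior_df * phi_bar) / (d + prior_df), 1)
    tstat <- out$coef / (out$se0 * sqrt(phi_mod))
    pv <- 2 * stats::pt(-abs(tstat), df = d + prior_df)
    out$p[fit_ok] <- ifelse(out$delta_pau[fit_ok] == 0, 1, pv[fit_ok])
  }
  out$coef <- out$se0 <- out$phi <- out$df_resid <- NULL
  tested <- is.na(out$reason) & !is.na(out$p)
  out$q[tested] <- stats::p.adjust(out$p[tested], "BH")

  # pooled per-arm PAU for the weighted-rank direction rule
  pau_pooled <- compute_pau_matrix(pooled, ann$exon_id)
  out <- adjust_direction(out, ann, pau_pooled, c("control", "depleted"))
  rownames(out) <- NULL
  out
}

#' Run the per-experiment dAPA test over a whole perturbation panel
#'
#' @param pcm [pas_count_matrix()] covering all panel samples.
#' @param design full design table.
#' @param ... passed to [dapa_perturbation()].
#' @return named list of per-experiment result data.frames.
#' @export
dapa_panel <- function(pcm, design, ...) {
  exps <- split(design, design$experiment_id)
  lapply(exps, function(d) dapa_perturbation(pcm, d, ...))
}

#' Per-RBP terminal-exon shortening/lengthening summary
#'
#' For each depletion experiment, significant proximal PAS (q below
#' `sig_q`) are rolled up to terminal exons, each exon voting once with its
#' dominant direction (sum of sign-adjusted delta PAU over its significant
#' pPAS).  A two-sided binomial test of shortening versus
#' shortening + lengthening counts at p = 0.5 is BH-corrected across
#' experiments and flagged at FDR < `fdr`.
#'
#' @param panel_results named list from [dapa_panel()].
#' @param design design table mapping experiments to RBPs and cell lines.
#' @param sig_q per-PAS significance threshold within an experiment.
#' @param fdr flag threshold on the BH-adjusted binomial p-values.
#' @return list with `summary` (one row per experiment: rbp_id, cell_line,
#'   n_significant, n_shortening, n_lengthening, log2_ratio,
#'   log2_ratio_pseudo, p_binomial, q_binomial, fdr_flag) and `effects`
#'   (named list of signed delta-PAU vectors over tested pPAS).
#' @export
rbp_effect_summary <- function(panel_results, design, sig_q = 0.05, fdr = 0.1) {
  meta <- unique(design[c("experiment_id", "cell_line", "target_rbp")])
  rows <- list(); effects <- list()
  for (exp_id in names(panel_results)) {
    res <- panel_results[[exp_id]]
    m <- meta[meta$experiment_id == exp_id, ]
    sig <- res[!is.na(res$q) & res$q < sig_q, , drop = FALSE]
    n_short <- n_long <- 0L
    if (nrow(sig)) {
      vote <- tapply(sig$delta_pau_signed, sig$exon_id, sum)
      n_short <- sum(vote > 0); n_long <- sum(vote < 0)
    }
    p_binom <- if (n_short + n_long > 0)
      stats::binom.test(n_short, n_short + n_long, 0.5)$p.value else NA_real_
    rows[[exp_id]] <- data.frame(
      experiment_id = exp_id, rbp_id = m$target_rbp, cell_line = m$cell_line,
      n_significant = nrow(sig), n_shortening = n_short, n_lengthening = n_long,
      log2_ratio = if (n_short > 0 && n_long > 0) log2(n_short / n_long) else NA_real_,
      log2_ratio_pseudo = log2((n_short + 0.5) / (n_long + 0.5)),
      p_binomial = p_binom, stringsAsFactors = FALSE)
    eff <- res$delta_pau_signed[is.na(res$reason)]
    names(eff) <- res$pas_id[is.na(res$reason)]
    effects[[exp_id]] <- eff
  }
  summary <- do.call(rbind, rows)
  summary$q_binomial <- NA_real_
  has_p <- !is.na(summary$p_binomial)
  summary$q_binomial[has_p] <- stats::p.adjust(summary$p_binomial[has_p], "BH")
  summary$fdr_flag <- !is.na(summary$q_binomial) & summary$q_binomial < fdr
  rownames(summary) <- NULL
  list(summary = summary, effects = effects)
}

#' Cosine similarity of per-RBP effect vectors between two cell lines
#'
#' Effect vectors (signed delta PAU over tested proximal PAS) of the same
#' RBP in two panels are restricted to shared pPAS; similarity is undefined
#' below 3 shared sites or when either restricted vector is all-zero.
#'
#' @param summary_a,summary_b outputs of [rbp_effect_summary()] for the two
#'   cell lines.
#' @return data.frame with rbp_id, n_shared, cosine, reason.
#' @export
cross_cellline_consistency <- function(summary_a, summary_b) {
  map_a <- stats::setNames(summary_a$summary$experiment_id, summary_a$summary$rbp_id)
  map_b <- stats::setNames(summary_b$summary$experiment_id, summary_b$summary$rbp_id)
  shared_rbps <- intersect(names(map_a), names(map_b))
  out <- lapply(shared_rbps, function(r) {
    va <- summary_a$effects[[map_a[[r]]]]
    vb <- summary_b$effects[[map_b[[r]]]]
    common <- intersect(names(va), names(vb))
    row <- data.frame(rbp_id = r, n_shared = length(common),
                      cosine = NA_real_, reason = NA_character_,
                      stringsAsFactors = FALSE)
    if (length(common) < 3) {
      row$reason <- "fewer than 3 shared pPAS"
      return(row)
    }
    a <- va[common]; b <- vb[common]
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) row$reason <- "all-zero effect vector"
    else row$cosine <- sum(a * b) / (na * nb)
    row
  })
  do.call(rbind, out)
}
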