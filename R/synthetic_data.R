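#' Configuration for the synthetic APA cohort / perturbation-panel generator
#'
#' The generator emulates the data structures of a tumor RNA-seq cohort and
#' an RBP-depletion panel: terminal exons carrying 2-3 tandem poly(A) sites,
#' negative-binomial exon totals scaled by log-normal library-size factors,
#' logistic-normal within-exon usage proportions whose proximal log-odds are
#' shifted by regulator activity, log-normal RBP expression tied to the same
#' latent regulator z-scores, CLIP evidence with false-positive/negative
#' rates, tumor purity, and exponential survival with a log-linear hazard in
#' purity and a latent APA factor.
#'
#' @param n_exons number of terminal exons.
#' @param pas_per_exon tandem PAS per exon (2 or 3).
#' @param n_samples_per_condition cohort samples per condition.
#' @param n_conditions number of cohort conditions (2 supported downstream).
#' @param n_rbps number of RBPs in the panel.
#' @param n_true_regulations number of planted (RBP, proximal PAS) regulations.
#' @param effect_size_logit shift in proximal-usage log-odds per unit
#'   regulator z-score.
#' @param rbp_condition_shift gap in the regulator z-score between the two
#'   cohort conditions for regulated RBPs (drives condition-level dAPA).
#' @param rbp_noise_sd per-sample standard deviation of regulator z-scores.
#' @param baseline_logit_sd SD of per-site baseline proximal log-odds.
#' @param logit_noise_sd SD of the per-(site, sample) logistic-normal noise.
#' @param apa_factor_loading loading of the latent per-sample APA factor on
#'   every proximal log-odds (induces a correlated usage axis).
#' @param exon_mean_count mean exon read total at unit library size.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param library_size_lognormal c(meanlog, sdlog) of library-size factors.
#' @param knockdown_factor multiplicative drop of target RBP expression upon
#'   depletion.
#' @param kd_z_shift drop (in z-score units) of the target regulator's
#'   activity in depleted arms.
#' @param n_replicates replicates per arm in each depletion experiment.
#' @param clip_fpr,clip_fnr false-positive / false-negative rates of the
#'   simulated CLIP evidence.
#' @param baseline_hazard,purity_coef,apa_coef exponential survival model:
#'   hazard = baseline_hazard * exp(purity_coef * purity + apa_coef * factor).
#' @param seed global seed; all sub-generators derive child seeds from it.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_exons = 200,
                              pas_per_exon = 2,
                              n_samples_per_condition = 60,
                              n_conditions = 2,
                              n_rbps = 20,
                              n_true_regulations = 20,
                              effect_size_logit = 1.5,
                              rbp_condition_shift = 1,
                              rbp_noise_sd = 0.5,
                              baseline_logit_sd = 0.5,
                              logit_noise_sd = 0.3,
                              apa_factor_loading = 0.25,
                              exon_mean_count = 200,
                              nb_dispersion = 0.15,
                              library_size_lognormal = c(0, 0.25),
                              knockdown_factor = 0.25,
                              kd_z_shift = 2,
                              n_replicates = 3,
                              clip_fpr = 0.05,
                              clip_fnr = 0.2,
                              baseline_hazard = 0.02,
                              purity_coef = -2,
                              apa_coef = 1,
                              seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_exons >= 1, pas_per_exon %in% c(2, 3),
            n_samples_per_condition >= 1, n_conditions >= 2,
            n_rbps >= 1, n_true_regulations >= 0,
            nb_dispersion > 0, exon_mean_count > 0,
            clip_fpr >= 0, clip_fpr <= 1, clip_fnr >= 0, clip_fnr <= 1,
            knockdown_factor > 0, n_replicates >= 2,
            baseline_hazard > 0, seed == round(seed))
  n_proximal <- n_exons * (pas_per_exon - 1)
  if (n_true_regulations > n_proximal)
    stop("n_true_regulations exceeds the number of proximal PAS (",
         n_proximal, "); each planted regulation uses a distinct pPAS")
  class(cfg) <- "simulation_config"
  cfg
}

# deterministic child seed, kept inside 32-bit integer range
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

# synthetic terminal-exon annotation: alternating strands, fixed layout
make_synthetic_annotation <- function(n_exons, pas_per_exon) {
  rows <- lapply(seq_len(n_exons), function(e) {
    strand <- if (e %% 2 == 1) "+" else "-"
    base <- e * 100000
    pos <- base + 1000 * seq_len(pas_per_exon)
    data.frame(pas_id = sprintf("e%04d_s%d", e, seq_len(pas_per_exon)),
               exon_id = sprintf("exon%04d", e),
               gene_id = sprintf("gene%04d", e),
               chrom = "chr1", start = pos, end = pos + 1, strand = strand,
               stringsAsFactors = FALSE)
  })
  ann <- assign_pas_ranks(do.call(rbind, rows))
  ann$pas_id <- sprintf("%s_p%d", ann$exon_id, ann$rank_from_5p)
  validate_pas_annotation(ann)
}

# PAS x sample counts from proximal logits: NB exon totals split multinomially
sample_pas_counts <- function(ann, logits, mu_exon, size_nb, lib_factor) {
  n_samp <- ncol(logits)
  counts <- matrix(0L, nrow(ann), n_samp,
                   dimnames = list(ann$pas_id, colnames(logits)))
  for (ex in split(seq_len(nrow(ann)), ann$exon_id)) {
    k <- length(ex)
    ord <- ex[order(ann$rank_from_5p[ex])]   # proximal first, distal last
    tot <- stats::rnbinom(n_samp, size = size_nb, mu = mu_exon * lib_factor)
    # usage proportions: softmax over (proximal logits, 0 for the distal site)
    lg <- rbind(logits[ann$pas_id[ord[-k]], , drop = FALSE], 0)
    pr <- exp(lg)
    pr <- sweep(pr, 2, colSums(pr), "/")
    for (s in seq_len(n_samp))
      counts[ord, s] <- stats::rmultinom(1, tot[s], pr[, s])[, 1]
  }
  counts
}

#' Simulate a tumor cohort with planted RBP-APA regulations
#'
#' Generates a PAS count matrix over two (or more) conditions, an RBP
#' expression matrix, a clinical table (purity, progression-free survival)
#' and the planted ground truth.  Regulated proximal PAS shift their usage
#' log-odds by `effect_size_logit` per unit z-score of their regulator; the
#' regulator z-scores of regulated RBPs differ between conditions by
#' `rbp_condition_shift`, so condition-level differential usage follows.
#'
#' @param config a [simulation_config()].
#' @return list with elements `counts` (`pas_count_matrix`), `rbp_expr`
#'   (RBP x sample matrix), `clinical` (data.frame), `condition` (0/1 vector
#'   per sample) and `truth` (regulations, latent factors, annotation).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(child_seed(config$seed, 1))
  ann <- make_synthetic_annotation(config$n_exons, config$pas_per_exon)
  n_samp <- config$n_samples_per_condition * config$n_conditions
  samples <- sprintf("S%03d", seq_len(n_samp))
  condition <- rep(seq_len(config$n_conditions) - 1L,
                   each = config$n_samples_per_condition)
  rbp_ids <- sprintf("RBP%02d", seq_len(config$n_rbps))

  proximal <- ann$pas_id[!ann$is_distal]
  reg_pas <- sample(proximal, config$n_true_regulations)
  reg_rbp <- sample(rbp_ids, config$n_true_regulations, replace = TRUE)
  reg_sign <- sample(c(-1, 1), config$n_true_regulations, replace = TRUE)
  regulations <- data.frame(
    rbp_id = reg_rbp, pas_id = reg_pas,
    exon_id = ann$exon_id[match(reg_pas, ann$pas_id)],
    direction = ifelse(reg_sign < 0, "proximal-up-on-depletion",
                       "proximal-down-on-depletion"),
    stringsAsFactors = FALSE)

  # latent regulator z-scores: condition gap for regulated RBPs plus noise
  z <- matrix(stats::rnorm(config$n_rbps * n_samp, 0, config$rbp_noise_sd),
              config$n_rbps, n_samp, dimnames = list(rbp_ids, samples))
  shifted <- rbp_ids %in% reg_rbp
  z[shifted, ] <- z[shifted, , drop = FALSE] +
    rep((condition - 0.5) * config$rbp_condition_shift, each = sum(shifted))

  # RBP expression tied to z
  base <- exp(stats::rnorm(config$n_rbps, 5, 0.5))
  rbp_expr <- base * exp(z + matrix(stats::rnorm(length(z), 0, 0.1),
                                    nrow(z), ncol(z)))
  dimnames(rbp_expr) <- dimnames(z)

  # latent APA axis, condition-independent by construction: centered within
  # each condition so no cohort-level usage shift leaks from this factor
  apa_factor <- stats::rnorm(n_samp)
  apa_factor <- apa_factor - stats::ave(apa_factor, condition)
  base_logit <- stats::rnorm(length(proximal), 0, config$baseline_logit_sd)
  names(base_logit) <- proximal
  logits <- matrix(base_logit, length(proximal), n_samp,
                   dimnames = list(proximal, samples))
  logits <- logits + config$apa_factor_loading *
    matrix(apa_factor, length(proximal), n_samp, byrow = TRUE)
  for (i in seq_len(nrow(regulations)))
    logits[regulations$pas_id[i], ] <- logits[regulations$pas_id[i], ] +
      reg_sign[i] * config$effect_size_logit * z[regulations$rbp_id[i], ]
  logits <- logits + matrix(stats::rnorm(length(logits), 0, config$logit_noise_sd),
                            nrow(logits), ncol(logits))

  lib_factor <- stats::rlnorm(n_samp, config$library_size_lognormal[1],
                              config$library_size_lognormal[2])
  counts <- sample_pas_counts(ann, logits, config$exon_mean_count,
                              1 / config$nb_dispersion, lib_factor)
  pcm <- pas_count_matrix(counts, ann)

  purity <- stats::rbeta(n_samp, 6, 3)
  hazard <- config$baseline_hazard *
    exp(config$purity_coef * purity + config$apa_coef * apa_factor)
  t_event <- stats::rexp(n_samp, hazard)
  t_cens <- stats::rexp(n_samp, config$baseline_hazard / 2)
  clinical <- data.frame(sample_id = samples,
                         time = pmin(t_event, t_cens),
                         event = as.integer(t_event <= t_cens),
                         purity = purity,
                         subtype = paste0("cond", condition),
                         stringsAsFactors = FALSE)

  truth <- list(regulations = regulations,
                z = z, apa_factor = apa_factor,
                true_survival_split = as.integer(apa_factor > stats::median(apa_factor)),
                rbp_ids = rbp_ids, annotation = ann,
                lib_factor = lib_factor)
  list(counts = pcm, rbp_expr = rbp_expr, clinical = clinical,
       condition = condition, truth = truth)
}

#' Simulate an RBP-depletion perturbation panel
#'
#' One experiment per RBP: `n_replicates` control and depleted replicates,
#' with the target RBP's expression multiplied by `knockdown_factor` and its
#' regulator z-score dropped by `kd_z_shift` in depleted arms, so regulated
#' proximal PAS shift their usage log-odds by
#' `effect_size_logit * kd_z_shift` in the direction planted in `truth`.
#'
#' @param config a [simulation_config()].
#' @param truth ground-truth element of [simulate_cohort()] output.
#' @param cell_line label written in the design table.
#' @param seed_offset vary to draw an independent panel (e.g. a second cell
#'   line) from the same config and truth.
#' @return list with `counts` (`pas_count_matrix`), `expr` (RBP x sample),
#'   `design` (data.frame).
#' @export
simulate_perturbation_panel <- function(config, truth, cell_line = "K562",
                                        seed_offset = 0) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(child_seed(config$seed, 2 + seed_offset))
  ann <- truth$annotation
  rbp_ids <- truth$rbp_ids
  n_rep <- config$n_replicates
  n_per_exp <- 2 * n_rep

  design <- do.call(rbind, lapply(seq_along(rbp_ids), function(i) {
    data.frame(experiment_id = sprintf("%s_exp%02d", cell_line, i),
               cell_line = cell_line, target_rbp = rbp_ids[i],
               sample_id = sprintf("%s_exp%02d_%s%d", cell_line, i,
                                   rep(c("ctl", "kd"), each = n_rep),
                                   rep(seq_len(n_rep), 2)),
               arm = rep(c("control", "depleted"), each = n_rep),
               replicate = rep(seq_len(n_rep), 2),
               stringsAsFactors = FALSE)
  }))

  proximal <- ann$pas_id[!ann$is_distal]
  base_logit <- stats::rnorm(length(proximal), 0, config$baseline_logit_sd)
  names(base_logit) <- proximal
  n_samp <- nrow(design)
  logits <- matrix(base_logit, length(proximal), n_samp,
                   dimnames = list(proximal, design$sample_id))

  # depleted arms: target regulator activity drops by kd_z_shift
  reg <- truth$regulations
  reg_sign <- ifelse(reg$direction == "proximal-up-on-depletion", -1, 1)
  z <- matrix(0, length(rbp_ids), n_samp,
              dimnames = list(rbp_ids, design$sample_id))
  kd <- design$arm == "depleted"
  z[cbind(match(design$target_rbp[kd], rbp_ids), which(kd))] <- -config$kd_z_shift
  for (i in seq_len(nrow(reg)))
    logits[reg$pas_id[i], ] <- logits[reg$pas_id[i], ] +
      reg_sign[i] * config$effect_size_logit * z[reg$rbp_id[i], ]
  logits <- logits + matrix(stats::rnorm(length(logits), 0, config$logit_noise_sd),
                            nrow(logits), ncol(logits))

  lib_factor <- stats::rlnorm(n_samp, config$library_size_lognormal[1],
                              config$library_size_lognormal[2])
  counts <- sample_pas_counts(ann, logits, config$exon_mean_count,
                              1 / config$nb_dispersion, lib_factor)

  base <- exp(stats::rnorm(length(rbp_ids), 5, 0.5))
  expr <- base * exp(matrix(stats::rnorm(length(rbp_ids) * n_samp, 0, 0.1),
                            length(rbp_ids), n_samp))
  dimnames(expr) <- list(rbp_ids, design$sample_id)
  expr[cbind(match(design$target_rbp[kd], rbp_ids), which(kd))] <-
    expr[cbind(match(design$target_rbp[kd], rbp_ids), which(kd))] *
    config$knockdown_factor

  list(counts = pas_count_matrix(counts, ann), expr = expr, design = design)
}

#' Simulate a CLIP binding-evidence table
#'
#' Every true (RBP, host exon) pair of a planted regulation is reported with
#' probability `1 - clip_fnr`; every other (RBP, exon) pair with probability
#' `clip_fpr`.
#'
#' @param truth ground-truth element of [simulate_cohort()] output.
#' @param clip_fpr,clip_fnr false-positive / false-negative rates.
#' @param seed integer seed.
#' @return data.frame with columns rbp_id, exon_id.
#' @export
simulate_clip <- function(truth, clip_fpr = 0.05, clip_fnr = 0.2, seed = 1) {
  stopifnot(clip_fpr >= 0, clip_fpr <= 1, clip_fnr >= 0, clip_fnr <= 1)
  set.seed(child_seed(seed, 3))
  exons <- unique(truth$annotation$exon_id)
  all_pairs <- expand.grid(rbp_id = truth$rbp_ids, exon_id = exons,
                           stringsAsFactors = FALSE)
  true_key <- unique(paste(truth$regulations$rbp_id, truth$regulations$exon_id))
  is_true <- paste(all_pairs$rbp_id, all_pairs$exon_id) %in% true_key
  keep <- ifelse(is_true,
                 stats::runif(nrow(all_pairs)) >= clip_fnr,
                 stats::runif(nrow(all_pairs)) < clip_fpr)
  out <- all_pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
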