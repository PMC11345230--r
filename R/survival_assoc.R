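#' Select feature sets for sample-relationship analysis
#'
#' Expression mode keeps the top `n_features` genes by median value; APA
#' mode keeps the top `n_features` proximal-PAS score rows with the fewest
#' zero (or missing) scores; combined mode takes floor(n/2) pPAS by fewest
#' zeros plus ceiling(n/2) genes by median expression.  Ties at a cutoff
#' are broken by feature id (lexicographic), so selection is deterministic.
#'
#' @param expr gene x sample matrix (normalized expression).
#' @param scores pPAS x sample normalized score matrix.
#' @param mode "expression", "apa" or "combined".
#' @param n_features total number of features to select.
#' @return feature x sample matrix of the selected rows.
#' @export
select_features <- function(expr, scores, mode = c("expression", "apa", "combined"),
                            n_features) {
  mode <- match.arg(mode)
  top_expr <- function(n) {
    if (n > nrow(expr)) stop("n_features exceeds available genes")
    med <- apply(expr, 1, stats::median, na.rm = TRUE)
    o <- order(-med, rownames(expr))
    expr[o[seq_len(n)], , drop = FALSE]
  }
  top_apa <- function(n) {
    if (n > nrow(scores)) stop("n_features exceeds available pPAS")
    nz <- rowSums(scores == 0 | is.na(scores))
    o <- order(nz, rownames(scores))
    scores[o[seq_len(n)], , drop = FALSE]
  }
  switch(mode,
         expression = top_expr(n_features),
         apa = top_apa(n_features),
         combined = rbind(top_apa(floor(n_features / 2)),
                          top_expr(ceiling(n_features / 2))))
}

#' PCA embedding of samples with a deterministic sign convention
#'
#' Centered (unscaled by default) principal components of the samples;
#' features containing missing values are dropped with a message.  Each
#' component's sign is fixed so that its largest-magnitude loading is
#' positive.
#'
#' @param features feature x sample matrix.
#' @param scale. logical, standardize features before PCA.
#' @return list of class `pc_result` with `coordinates` (samples x k),
#'   `variance_explained` (fraction per component, non-increasing) and
#'   `loadings`.
#' @export
pca_embed <- function(features, scale. = FALSE) {
  keep <- rowSums(is.na(features)) == 0
  if (!all(keep))
    message(sum(!keep), " features with missing values dropped before PCA")
  x <- t(features[keep, , drop = FALSE])
  p <- stats::prcomp(x, center = TRUE, scale. = scale.)
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  structure(list(coordinates = p$x,
                 variance_explained = p$sdev^2 / sum(p$sdev^2),
                 loadings = p$rotation),
            class = "pc_result")
}

#' Kendall correlation with a percentile bootstrap confidence interval
#'
#' Kendall's tau-b between paired observations, with a seeded percentile
#' bootstrap (resampling pairs) for the 95 percent interval.
#'
#' @param x,y paired numeric vectors, n >= 10.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed for the resampling.
#' @param conf confidence level.
#' @return list with tau, ci_low, ci_high, n_boot; tau is NA with a reason
#'   when either input is constant.
#' @export
kendall_with_ci <- function(x, y, n_boot = 1000, seed = 1, conf = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 10)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(tau = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                reason = "constant input"))
  tau <- stats::cor(x, y, method = "kendall")
  set.seed(seed)
  n <- length(x)
  boots <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) return(NA_real_)
    stats::cor(x[i], y[i], method = "kendall")
  }, 0)
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  list(tau = tau, ci_low = qs[1], ci_high = qs[2], n_boot = n_boot)
}

#' Rank-threshold log-rank scan of a continuous feature against survival
#'
#' Values are transformed to ascending ranks (ties broken by sample id, so
#' ranks are a permutation of 1..n) and every threshold t in
#' `[min_group, n - min_group]` splits the samples into rank <= t versus
#' rank > t; a two-sample log-rank test is run at each threshold.  The scan
#' is invariant to strictly monotone transforms of the values.
#'
#' @param values numeric feature per sample.
#' @param time,event survival endpoint (time >= 0, event 0/1).
#' @param min_group minimal group size on either side of a threshold.
#' @param sample_id optional ids used for deterministic tie-breaking;
#'   defaults to the element order.
#' @return list of class `scan_result`: `rank_threshold`, `p` (per
#'   threshold), `flag` (TRUE where a threshold had no events in a group
#'   and p was recorded as 1), `median_p`, `best_threshold` (argmin p,
#'   smallest on ties), `ranks`.
#' @export
logrank_scan <- function(values, time, event, min_group = 30,
                         sample_id = NULL) {
  n <- length(values)
  stopifnot(length(time) == n, length(event) == n, n >= 2 * min_group)
  if (is.null(sample_id)) sample_id <- seq_len(n)
  ranks <- integer(n)
  ranks[order(values, sample_id)] <- seq_len(n)
  thresholds <- seq.int(min_group, n - min_group)
  p <- numeric(length(thresholds))
  flag <- logical(length(thresholds))
  for (k in seq_along(thresholds)) {
    g <- ranks <= thresholds[k]
    if (sum(event[g]) == 0 || sum(event[!g]) == 0) {
      p[k] <- 1; flag[k] <- TRUE
      next
    }
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    p[k] <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  }
  structure(list(rank_threshold = thresholds, p = p, flag = flag,
                 median_p = stats::median(p),
                 best_threshold = thresholds[which.min(p)],
                 ranks = ranks),
            class = "scan_result")
}

#' Four-group survival stratification on two continuous axes
#'
#' Crosses (purity <= / > t_purity) with (pc <= / > t_pc) into up to four
#' groups and tests identical survival functions with a K-sample log-rank
#' test.  When a threshold is not supplied, it is chosen as the value at
#' the argmin-p rank threshold of a [logrank_scan()] on that axis.  Empty
#' groups are dropped (degenerate axes collapse to fewer groups); at least
#' two nonempty groups are required.
#'
#' @param purity,pc_values numeric axes per sample.
#' @param time,event survival endpoint.
#' @param t_purity,t_pc optional value thresholds.
#' @param min_group passed to [logrank_scan()] when scanning for a
#'   threshold.
#' @return list with `groups` (labels "loLo", "loHi", "hiLo", "hiHi"),
#'   `p` (K-sample log-rank), `df`, `t_purity`, `t_pc`.
#' @export
four_group_split <- function(purity, pc_values, time, event,
                             t_purity = NULL, t_pc = NULL, min_group = 30) {
  n <- length(purity)
  stopifnot(length(pc_values) == n, length(time) == n, length(event) == n)
  pick <- function(v) {
    sc <- logrank_scan(v, time, event, min_group)
    sort(v)[sc$best_threshold]
  }
  if (is.null(t_purity)) t_purity <- pick(purity)
  if (is.null(t_pc)) t_pc <- pick(pc_values)
  if (t_purity < min(purity) || t_purity >= max(purity) ||
      t_pc < min(pc_values) || t_pc >= max(pc_values))
    stop("thresholds must lie inside the data range")
  lab <- paste0(ifelse(purity <= t_purity, "lo", "hi"),
                ifelse(pc_values <= t_pc, "Lo", "Hi"))
  lab <- factor(lab)
  lab <- droplevels(lab)
  if (nlevels(lab) < 2) stop("stratification produced a single group")
  sd <- survival::survdiff(survival::Surv(time, event) ~ lab)
  df <- nlevels(lab) - 1L
  list(groups = as.character(lab),
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE),
       df = df, t_purity = t_purity, t_pc = t_pc)
}
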