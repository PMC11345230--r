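#' Replicate-pair outlier filter on a low-dimensional embedding
#'
#' Embeds the samples (PCA by default, first `embed_dims` components),
#' computes the Euclidean distance between the members of each replicate
#' pair and removes pairs whose distance strictly exceeds
#' `q75 + 1.5 * IQR` of the pair-distance distribution.  Pairs sitting
#' exactly at the threshold are retained.
#'
#' @param features samples x k numeric matrix (rownames = sample ids).
#' @param pairs two-column matrix or data.frame of sample-id pairs.
#' @param embed_dims number of embedding components (>= 2).
#' @param embed_fun function(features, k) -> samples x k coordinates;
#'   defaults to centered PCA.  Supply an alternative embedding (and take
#'   the union of flagged pairs across calls) to filter on several
#'   representations.
#' @return list with `retained` (pair index vector), `removed`, `distances`,
#'   and `rule` (q75, iqr, threshold).
#' @export
pair_outlier_filter <- function(features, pairs, embed_dims = 2,
                                embed_fun = NULL) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 4) stop("need at least 4 pairs to define the outlier rule")
  stopifnot(embed_dims >= 2)
  if (!all(pairs %in% rownames(features)))
    stop("pair members missing from the feature matrix")
  if (is.null(embed_fun))
    embed_fun <- function(f, k) {
      p <- stats::prcomp(f, center = TRUE, scale. = FALSE)
      p$x[, seq_len(min(k, ncol(p$x))), drop = FALSE]
    }
  emb <- embed_fun(features, embed_dims)
  d <- unname(sqrt(rowSums((emb[pairs[, 1], , drop = FALSE] -
                            emb[pairs[, 2], , drop = FALSE])^2)))
  q75 <- unname(stats::quantile(d, 0.75))
  iqr <- unname(stats::IQR(d))
  thr <- q75 + 1.5 * iqr
  removed <- which(d > thr)
  list(retained = setdiff(seq_len(nrow(pairs)), removed),
       removed = removed, distances = d,
       rule = list(q75 = q75, iqr = iqr, threshold = thr))
}

#' Filter PAS whose scores fluctuate strongly within control samples
#'
#' Per PAS and control group, a dispersion statistic of the normalized
#' scores (IQR by default) is computed; a PAS is dropped when its statistic
#' strictly exceeds the cutoff in any group, or when a whole group has no
#' defined scores.  The default cutoff is the 90th percentile of the
#' per-PAS maximal group statistics.
#'
#' @param scores PAS x samples normalized score matrix restricted to
#'   control samples.
#' @param groups control-group label per column (e.g. cell line).
#' @param dispersion_stat function(numeric) -> scalar; default [stats::IQR]
#'   over non-missing values.
#' @param cutoff numeric threshold; NULL for the percentile default.
#' @return list with `retained`, `dropped` (data.frame pas_id, reason,
#'   statistic) and `cutoff`.
#' @export
unstable_pas_filter <- function(scores, groups, dispersion_stat = NULL,
                                cutoff = NULL) {
  stopifnot(ncol(scores) == length(groups))
  if (any(table(groups) < 4))
    stop("need at least 4 control samples per group")
  if (is.null(dispersion_stat))
    dispersion_stat <- function(v) stats::IQR(v, na.rm = TRUE)
  grp <- split(seq_along(groups), groups)
  stat <- matrix(NA_real_, nrow(scores), length(grp),
                 dimnames = list(rownames(scores), names(grp)))
  no_data <- rep(FALSE, nrow(scores))
  for (g in seq_along(grp)) {
    sub <- scores[, grp[[g]], drop = FALSE]
    all_na <- rowSums(!is.na(sub)) == 0
    no_data <- no_data | all_na
    stat[!all_na, g] <- apply(sub[!all_na, , drop = FALSE], 1, dispersion_stat)
  }
  max_stat <- apply(stat, 1, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  if (is.null(cutoff))
    cutoff <- unname(stats::quantile(max_stat, 0.9, na.rm = TRUE))
  unstable <- !is.na(max_stat) & max_stat > cutoff
  dropped <- data.frame(
    pas_id = rownames(scores)[no_data | unstable],
    reason = ifelse(no_data[no_data | unstable], "no data", "unstable"),
    statistic = max_stat[no_data | unstable],
    stringsAsFactors = FALSE)
  list(retained = rownames(scores)[!(no_data | unstable)],
       dropped = dropped, cutoff = cutoff)
}
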