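#' Relative poly(A) site usage within a terminal exon
#'
#' PAU of a site is the fraction of the exon's reads supporting it.  For a
#' zero-coverage exon all PAU values are undefined (NA).
#'
#' @param counts non-negative integer vector over one exon's PAS.
#' @return numeric vector of fractions summing to 1, or all-NA with
#'   attribute `zero_coverage = TRUE` when the exon has no reads.
#' @export
compute_pau <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- sum(counts)
  if (tot == 0) {
    out <- rep(NA_real_, length(counts))
    attr(out, "zero_coverage") <- TRUE
    return(out)
  }
  counts / tot
}

#' PAU matrix over all exons and samples
#'
#' @param counts PAS x samples count matrix.
#' @param exon_ids exon identifier per row of `counts`.
#' @return matrix of the same shape; NA wherever the exon total is zero.
#' @export
compute_pau_matrix <- function(counts, exon_ids) {
  stopifnot(nrow(counts) == length(exon_ids))
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- rowsum(counts, exon_ids)[exon_ids, , drop = FALSE]
  pau <- counts / tot
  pau[tot == 0] <- NA_real_
  pau
}

#' Signed binomial usage score of a poly(A) site
#'
#' Given M reads supporting the site and N reads supporting all sites of the
#' exon, two one-sided binomial tail tests against Binomial(N, 0.5) are
#' combined into `score = -log10 P(m > M) + log10 P(m < M)` (strict
#' inequalities; the point mass at M belongs to neither tail).  The score is
#' 0 for a perfectly balanced site, grows to +Inf as the site dominates the
#' exon and to -Inf as it vanishes; both tails are clamped at the smallest
#' positive normal double so scores stay finite.
#'
#' @param M reads supporting the PAS (vectorized).
#' @param N total reads over the exon's PAS.
#' @return signed numeric score(s).
#' @export
pas_score <- function(M, N) {
  if (any(N < 1)) stop("N must be >= 1")
  if (any(M < 0) || any(M > N)) stop("M must satisfy 0 <= M <= N")
  eps <- .Machine$double.xmin
  # both tails via the lower tail and the p = 0.5 symmetry
  # P(m > M) = P(m < N - M), so antisymmetry in M <-> N - M is exact
  pval1 <- pmin(pmax(stats::pbinom(N - M - 1, N, 0.5), eps), 1)
  pval2 <- pmin(pmax(stats::pbinom(M - 1, N, 0.5), eps), 1)
  -log10(pval1) + log10(pval2)
}

#' Signed usage-score matrix for all PAS and samples
#'
#' @inheritParams compute_pau_matrix
#' @return matrix of scores; NA where the exon total is zero.
#' @export
pas_score_matrix <- function(counts, exon_ids) {
  stopifnot(nrow(counts) == length(exon_ids))
  tot <- rowsum(counts, exon_ids)[exon_ids, , drop = FALSE]
  out <- matrix(NA_real_, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  ok <- tot > 0
  out[ok] <- pas_score(counts[ok], tot[ok])
  out
}

#' Median-of-ratios size factors
#'
#' Each row of the count matrix is divided by its row median; the size
#' factor of sample k is the median of column k of the ratio matrix.  Rows
#' without a positive median are excluded from the estimate.
#'
#' @param counts PAS x samples count matrix.
#' @return positive numeric vector, one per sample, attribute `n_rows_used`.
#' @export
size_factors <- function(counts) {
  med <- apply(counts, 1, stats::median)
  use <- which(med > 0)
  if (!length(use)) stop("no informative rows: every row median is zero")
  ratios <- counts[use, , drop = FALSE] / med[use]
  sf <- apply(ratios, 2, stats::median)
  if (any(sf <= 0)) stop("non-positive size factor; matrix too sparse")
  attr(sf, "n_rows_used") <- length(use)
  sf
}

#' Library-size control of usage scores by quantile-regression residuals
#'
#' Per PAS, a median (tau = 0.5) regression of |score| on library size is
#' fitted across samples; positive residuals become the normalized score
#' magnitudes (negative residuals are zeroed) and the sign of the original
#' score is restored.  PAS with fewer than `min_samples` defined scores get
#' all-NA normalized scores.
#'
#' @param scores PAS x samples signed score matrix (NA allowed).
#' @param library_size positive numeric per sample.
#' @param min_samples minimum defined scores required to fit one PAS.
#' @return list with `score` (input), `normalized_score` (same shape) and
#'   `skipped` (pas ids not fitted).
#' @export
normalize_scores <- function(scores, library_size, min_samples = 8) {
  stopifnot(length(library_size) == ncol(scores), all(library_size > 0))
  norm <- matrix(NA_real_, nrow(scores), ncol(scores), dimnames = dimnames(scores))
  skipped <- character(0)
  for (i in seq_len(nrow(scores))) {
    ok <- which(!is.na(scores[i, ]))
    if (length(ok) < min_samples) {
      skipped <- c(skipped, rownames(scores)[i])
      next
    }
    y <- abs(scores[i, ok])
    x <- library_size[ok]
    resid <- if (stats::sd(y) == 0) {
      rep(0, length(ok))          # flat median fit: all residuals zero
    } else {
      fit <- tryCatch(
        suppressWarnings(quantreg::rq(y ~ x, tau = 0.5)),
        error = function(e) NULL)
      if (is.null(fit)) y - stats::median(y) else stats::residuals(fit)
    }
    norm[i, ok] <- pmax(resid, 0) * sign(scores[i, ok])
  }
  list(score = scores, normalized_score = norm, skipped = skipped)
}
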