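#' Cohort association between PAS usage scores and RBP expression
#'
#' For every RBP the cohort is split into low- and high-expression halves
#' (median split by default; tertile split compares the bottom and top
#' thirds) and, per proximal PAS, the normalized usage scores of the two
#' cohorts are compared with a two-sided Mann-Whitney test.  BH correction
#' runs over all (PAS, RBP) pairs; the direction is the sign of the median
#' score difference (low minus high cohort).
#'
#' @param scores pPAS x samples normalized score matrix.
#' @param rbp_expr RBP x samples expression matrix (same samples).
#' @param split "median" or "tertile".
#' @param min_per_cohort minimum cohort size after the split.
#' @return data.frame with pas_id, rbp_id, p, q, direction (-1/0/1),
#'   median_low, median_high.
#' @export
cohort_association <- function(scores, rbp_expr, split = c("median", "tertile"),
                               min_per_cohort = 10) {
  split <- match.arg(split)
  stopifnot(ncol(scores) == ncol(rbp_expr))
  n <- ncol(scores)
  ord_ids <- colnames(rbp_expr)
  rows <- vector("list", nrow(rbp_expr) * nrow(scores))
  k <- 0L
  for (r in seq_len(nrow(rbp_expr))) {
    o <- order(rbp_expr[r, ], ord_ids)      # ties broken by sample id
    cut_lo <- if (split == "median") floor(n / 2) else floor(n / 3)
    lo <- o[seq_len(cut_lo)]
    hi <- if (split == "median") o[(cut_lo + 1):n] else o[(n - cut_lo + 1):n]
    if (min(length(lo), length(hi)) < min_per_cohort)
      stop("cohort split leaves fewer than ", min_per_cohort, " samples")
    for (i in seq_len(nrow(scores))) {
      a <- scores[i, lo]; b <- scores[i, hi]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      k <- k + 1L
      if (!length(a) || !length(b)) {
        rows[[k]] <- data.frame(pas_id = rownames(scores)[i],
                                rbp_id = rownames(rbp_expr)[r],
                                p = NA_real_, q = NA_real_, direction = NA_real_,
                                median_low = NA_real_, median_high = NA_real_,
                                stringsAsFactors = FALSE)
        next
      }
      ml <- stats::median(a); mh <- stats::median(b)
      p <- if (stats::sd(c(a, b)) == 0) 1 else
        suppressWarnings(stats::wilcox.test(a, b)$p.value)
      rows[[k]] <- data.frame(pas_id = rownames(scores)[i],
                              rbp_id = rownames(rbp_expr)[r],
                              p = p, q = NA_real_, direction = sign(ml - mh),
                              median_low = ml, median_high = mh,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  tested <- !is.na(out$p)
  out$q[tested] <- stats::p.adjust(out$p[tested], "BH")
  out
}

#' Chi-square co-variation test between dAPA and RBP DE status
#'
#' Tests independence of a proximal PAS's differential-usage status and an
#' RBP's differential-expression status across all panel experiments on a
#' 3x3 contingency table (up / down / nonsig on both margins).  Margins
#' whose levels are entirely empty are collapsed; a table degenerating
#' below 2x2 is untested.
#'
#' @param apa_status,de_status character vectors in {"up","down","nonsig"}
#'   over the same experiments.
#' @param min_experiments minimum panel size.
#' @return list with chi2, p, df, reason (NA when tested).
#' @export
co_test <- function(apa_status, de_status, min_experiments = 20) {
  stopifnot(length(apa_status) == length(de_status))
  if (length(apa_status) < min_experiments)
    stop("need at least ", min_experiments, " experiments")
  lv <- c("up", "down", "nonsig")
  tab <- table(factor(de_status, lv), factor(apa_status, lv))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    return(list(chi2 = NA_real_, p = NA_real_, df = NA_integer_,
                reason = "contingency table below 2x2"))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = ct$p.value,
       df = unname(ct$parameter), reason = NA_character_)
}

#' dAPA status of every proximal PAS in every panel experiment
#'
#' @param panel_results named list from [dapa_panel()].
#' @param alpha per-experiment q-value threshold.
#' @return character matrix pPAS x experiments in {"up","down","nonsig"}
#'   (NA where untested); status refers to the sign of the raw delta PAU
#'   upon depletion.
#' @export
dapa_status_matrix <- function(panel_results, alpha = 0.05) {
  pas <- panel_results[[1]]$pas_id
  out <- matrix(NA_character_, length(pas), length(panel_results),
                dimnames = list(pas, names(panel_results)))
  for (e in names(panel_results)) {
    res <- panel_results[[e]]
    st <- ifelse(is.na(res$q), NA_character_,
                 ifelse(res$q < alpha & res$delta_pau > 0, "up",
                        ifelse(res$q < alpha & res$delta_pau < 0, "down",
                               "nonsig")))
    out[res$pas_id, e] <- st
  }
  out
}

#' Differential-expression status of genes within one depletion experiment
#'
#' Transparent pluggable caller: counts are normalized by median-of-ratios
#' size factors (column-sum ratios as fallback for degenerate matrices), a
#' two-sample equal-variance t-test on log2 values is combined with a
#' log2-fold-change gate (both `q < alpha` and `|LFC| > lfc_threshold`
#' required).  Experiments in which the target RBP does not come out "down"
#' fail the depletion sanity gate (`gate_pass` attribute).
#'
#' @param expr gene x sample count matrix containing the experiment's
#'   samples.
#' @param design design rows for one experiment.
#' @param alpha BH-adjusted significance threshold.
#' @param lfc_threshold absolute log2-fold-change gate.
#' @return data.frame gene_id, lfc, p, q, status; attribute `gate_pass`.
#' @export
de_status <- function(expr, design, alpha = 0.05, lfc_threshold = 1) {
  design <- design[design$sample_id %in% colnames(expr), , drop = FALSE]
  if (any(table(design$arm) < 2)) stop("need >= 2 replicates per arm")
  sub <- expr[, design$sample_id, drop = FALSE]
  sf <- tryCatch(size_factors(sub),
                 error = function(e) colSums(sub) / mean(colSums(sub)))
  lg <- log2(sweep(sub, 2, sf, "/") + 0.5)
  ctl <- design$arm == "control"
  lfc <- rowMeans(lg[, !ctl, drop = FALSE]) - rowMeans(lg[, ctl, drop = FALSE])
  p <- vapply(seq_len(nrow(lg)), function(i) {
    a <- lg[i, ctl]; b <- lg[i, !ctl]
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(if (mean(b) == mean(a)) 1 else 0)
    stats::t.test(b, a, var.equal = TRUE)$p.value
  }, 0)
  q <- stats::p.adjust(p, "BH")
  status <- ifelse(q < alpha & lfc > lfc_threshold, "up",
                   ifelse(q < alpha & lfc < -lfc_threshold, "down", "nonsig"))
  out <- data.frame(gene_id = rownames(expr), lfc = lfc, p = p, q = q,
                    status = status, stringsAsFactors = FALSE)
  target <- design$target_rbp[1]
  attr(out, "gate_pass") <- target %in% out$gene_id &&
    out$status[out$gene_id == target] == "down"
  out
}

#' DE status of every RBP in every panel experiment
#'
#' Applies [de_status()] per experiment and drops experiments failing the
#' depletion sanity gate (target RBP not significantly down).
#'
#' @param expr RBP x sample count/expression matrix for the panel.
#' @param design full panel design table.
#' @param ... passed to [de_status()].
#' @return list with `status` (RBP x retained experiments character matrix)
#'   and `excluded` (experiment ids failing the gate).
#' @export
de_status_matrix <- function(expr, design, ...) {
  exps <- split(design, design$experiment_id)
  status <- matrix(NA_character_, nrow(expr), length(exps),
                   dimnames = list(rownames(expr), names(exps)))
  excluded <- character(0)
  for (e in names(exps)) {
    res <- de_status(expr, exps[[e]], ...)
    if (!attr(res, "gate_pass")) {
      excluded <- c(excluded, e)
      next
    }
    status[res$gene_id, e] <- res$status
  }
  list(status = status[, setdiff(names(exps), excluded), drop = FALSE],
       excluded = excluded)
}

#' Panel-wide co-variation tests for all (pPAS, RBP) pairs
#'
#' @param apa_status pPAS x experiments matrix from [dapa_status_matrix()].
#' @param de_status RBP x experiments matrix from [de_status_matrix()].
#' @param min_experiments minimum experiments with both statuses defined.
#' @return data.frame pas_id, rbp_id, chi2, p, q, reason; BH over tested
#'   pairs.
#' @export
co_tests <- function(apa_status, de_status, min_experiments = 20) {
  common <- intersect(colnames(apa_status), colnames(de_status))
  rows <- list()
  for (i in seq_len(nrow(apa_status))) for (r in seq_len(nrow(de_status))) {
    a <- apa_status[i, common]; d <- de_status[r, common]
    ok <- !is.na(a) & !is.na(d)
    row <- data.frame(pas_id = rownames(apa_status)[i],
                      rbp_id = rownames(de_status)[r],
                      chi2 = NA_real_, p = NA_real_, q = NA_real_,
                      reason = NA_character_, stringsAsFactors = FALSE)
    if (sum(ok) < min_experiments) {
      row$reason <- "too few experiments"
    } else {
      ct <- co_test(a[ok], d[ok], min_experiments)
      row$chi2 <- ct$chi2; row$p <- ct$p; row$reason <- ct$reason
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  tested <- !is.na(out$p)
  out$q[tested] <- stats::p.adjust(out$p[tested], "BH")
  out
}

#' Classify (pPAS, RBP) pairs by CLIP, PERT and CO evidence
#'
#' Assembles one record per cohort-tested pair: CLIP evidence joined via
#' the pPAS's host exon; PERT if the pPAS responds (q < `pert_alpha`) in
#' any retained depletion experiment targeting the RBP, with the
#' perturbation direction taken from the most significant such experiment;
#' CO from the panel-wide chi-square at FDR < `co_alpha`.  A pair is
#' `significant` when its cohort q-value is below `cohort_alpha` and
#' `consistent` when it has PERT evidence whose depletion direction equals
#' the low-minus-high cohort direction (depletion mimics the low-expression
#' extreme).  The category string is the exact set of evidence flags, or
#' "OTHER" when no CLIP/PERT/CO evidence exists.
#'
#' @param cohort_res output of [cohort_association()].
#' @param panel_results named list from [dapa_panel()] (retained
#'   experiments only).
#' @param design panel design table.
#' @param clip CLIP table (rbp_id, exon_id).
#' @param co_res output of [co_tests()] (optional; NULL disables CO).
#' @param ann `pas_annotation` data.frame.
#' @param pert_alpha,co_alpha,cohort_alpha evidence thresholds.
#' @return data.frame of association records, one row per tested pair.
#' @export
classify_pairs <- function(cohort_res, panel_results, design, clip, co_res,
                           ann, pert_alpha = 0.05, co_alpha = 0.05,
                           cohort_alpha = 0.05) {
  recs <- cohort_res[!is.na(cohort_res$p), , drop = FALSE]
  recs$exon_id <- ann$exon_id[match(recs$pas_id, ann$pas_id)]
  clip_key <- paste(clip$rbp_id, clip$exon_id)
  recs$clip <- paste(recs$rbp_id, recs$exon_id) %in% clip_key

  meta <- unique(design[c("experiment_id", "target_rbp")])
  meta <- meta[meta$experiment_id %in% names(panel_results), , drop = FALSE]
  recs$pert <- FALSE
  recs$pert_direction <- 0
  for (j in seq_len(nrow(recs))) {
    exps <- meta$experiment_id[meta$target_rbp == recs$rbp_id[j]]
    best_q <- Inf; best_dir <- 0
    for (e in exps) {
      res <- panel_results[[e]]
      i <- match(recs$pas_id[j], res$pas_id)
      if (is.na(i) || is.na(res$q[i])) next
      if (res$q[i] < pert_alpha && res$q[i] < best_q) {
        best_q <- res$q[i]; best_dir <- sign(res$delta_pau[i])
      }
    }
    recs$pert[j] <- is.finite(best_q)
    recs$pert_direction[j] <- best_dir
  }

  recs$co <- FALSE
  if (!is.null(co_res)) {
    co_key <- paste(co_res$pas_id, co_res$rbp_id)
    co_sig <- !is.na(co_res$q) & co_res$q < co_alpha
    recs$co <- paste(recs$pas_id, recs$rbp_id) %in% co_key[co_sig]
  }

  recs$significant <- recs$q < cohort_alpha
  recs$consistent <- recs$pert & recs$pert_direction != 0 &
    recs$direction != 0 & recs$pert_direction == recs$direction
  flags <- cbind(CLIP = recs$clip, PERT = recs$pert, CO = recs$co)
  recs$category <- apply(flags, 1, function(f)
    if (!any(f)) "OTHER" else paste(colnames(flags)[f], collapse = "+"))
  rownames(recs) <- NULL
  recs
}

#' Count association records per category, significance and consistency
#'
#' @param records output of [classify_pairs()].
#' @return data.frame with one row per category: n, n_significant,
#'   n_consistent.
#' @export
category_summary <- function(records) {
  out <- do.call(rbind, lapply(split(records, records$category), function(g)
    data.frame(category = g$category[1], n = nrow(g),
               n_significant = sum(g$significant),
               n_consistent = sum(g$consistent & g$significant),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
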