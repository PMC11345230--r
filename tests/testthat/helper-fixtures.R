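# shared fixtures built in code

# minimal two-site exon annotation on a chosen strand
two_site_exon <- function(strand = "+", exon_id = "exonA") {
  assign_pas_ranks(data.frame(
    pas_id = c("p1", "p2"), exon_id = exon_id, gene_id = "geneA",
    chrom = "chr1", start = c(100, 900), end = c(101, 901), strand = strand,
    stringsAsFactors = FALSE))
}

# exact binomial-tail oracle for the PAS score, by pmf summation
oracle_pas_score <- function(M, N) {
  pmf <- stats::dbinom(0:N, N, 0.5)
  p1 <- if (M < N) sum(pmf[(M + 2):(N + 1)]) else 0
  p2 <- if (M > 0) sum(pmf[1:M]) else 0
  eps <- .Machine$double.xmin
  -log10(min(max(p1, eps), 1)) + log10(min(max(p2, eps), 1))
}

# noiseless count matrix realizing r_pas = b0 * r_other (+ b1 * D * r_other)
exact_fit_pcm <- function(b0, b1, n_per_cond = 12) {
  x <- rep(4 * seq_len(n_per_cond), 2)          # r_other per sample
  cond <- rep(0:1, each = n_per_cond)
  y <- b0 * x + b1 * cond * x
  stopifnot(all(y == round(y)))
  n_exons <- 1L
  ann <- two_site_exon("+")
  counts <- rbind(p1 = y, p2 = x)
  colnames(counts) <- sprintf("S%02d", seq_along(x))
  list(pcm = pas_count_matrix(counts, ann), cond = cond,
       sf = rep(1, length(x)))
}

# tiny perturbation-panel result table for roll-up tests
fake_dapa_result <- function(exon_dirs, q = 0.01) {
  n <- length(exon_dirs)
  if (n == 0)
    return(data.frame(pas_id = character(), exon_id = character(),
                      delta_pau = numeric(), p = numeric(), q = numeric(),
                      reason = character(), direction = character(),
                      delta_pau_signed = numeric(), stringsAsFactors = FALSE))
  data.frame(
    pas_id = sprintf("e%03d_p1", seq_len(n)),
    exon_id = sprintf("e%03d", seq_len(n)),
    delta_pau = exon_dirs * 0.2, p = q, q = q,
    reason = NA_character_,
    direction = ifelse(exon_dirs > 0, "shortening",
                       ifelse(exon_dirs < 0, "lengthening", "none")),
    delta_pau_signed = exon_dirs * 0.2,
    stringsAsFactors = FALSE)
}
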