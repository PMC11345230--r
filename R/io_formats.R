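#' Assign strand-aware ranks and the distal flag to poly(A) sites
#'
#' Orders the PAS of each terminal exon in transcript 5'->3' orientation
#' (ascending genomic start on the plus strand, descending on the minus
#' strand), assigns `rank_from_5p` 1..k and marks the single most 3' site of
#' each exon as distal.  All other sites are proximal.
#'
#' @param pas data.frame with at least columns `pas_id`, `exon_id`, `chrom`,
#'   `start`, `end`, `strand`.
#' @return The input with `rank_from_5p` (integer) and `is_distal` (logical)
#'   columns added, rows ordered by exon then rank.
#' @export
assign_pas_ranks <- function(pas) {
  stopifnot(is.data.frame(pas),
            all(c("pas_id", "exon_id", "start", "end", "strand") %in% names(pas)))
  if (any(pas$start >= pas$end))
    stop("PAS intervals must satisfy start < end (0-based half-open)")
  if (!all(pas$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  pieces <- lapply(split(pas, pas$exon_id), function(ex) {
    ord <- if (ex$strand[1] == "+") order(ex$start) else order(-ex$start)
    ex <- ex[ord, , drop = FALSE]
    ex$rank_from_5p <- seq_len(nrow(ex))
    ex$is_distal <- ex$rank_from_5p == nrow(ex)
    ex
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Validate a PAS annotation table
#'
#' Checks the structural invariants of a PAS annotation: per exon the ranks
#' are a permutation of 1..k consistent with transcript orientation, exactly
#' one distal site per exon (the maximal rank), and start < end.
#'
#' @param pas data.frame as produced by [assign_pas_ranks()].
#' @return The validated data.frame, invisibly classed `pas_annotation`.
#' @export
validate_pas_annotation <- function(pas) {
  req <- c("pas_id", "exon_id", "chrom", "start", "end", "strand",
           "rank_from_5p", "is_distal")
  miss <- setdiff(req, names(pas))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(pas$start >= pas$end)) stop("start must be < end")
  for (ex in split(pas, pas$exon_id)) {
    k <- nrow(ex)
    if (!setequal(ex$rank_from_5p, seq_len(k)))
      stop("exon ", ex$exon_id[1], ": ranks are not a permutation of 1..", k)
    if (sum(ex$is_distal) != 1L)
      stop("exon ", ex$exon_id[1], ": must have exactly one distal PAS")
    if (ex$rank_from_5p[ex$is_distal] != k)
      stop("exon ", ex$exon_id[1], ": distal PAS must carry the maximal rank")
    ord <- if (ex$strand[1] == "+") order(ex$start) else order(-ex$start)
    if (!identical(ex$rank_from_5p[ord], seq_len(k)))
      stop("exon ", ex$exon_id[1], ": rank order disagrees with strand")
  }
  class(pas) <- unique(c("pas_annotation", class(pas)))
  invisible(pas)
}

#' Read a PAS atlas in BED format and place sites into terminal exons
#'
#' Parses a BED6 file of poly(A) sites, assigns each site to at most one
#' terminal exon by same-strand interval overlap (greatest overlap wins;
#' exact ties are dropped with a warning), and derives strand-aware
#' proximal/distal ranks within each exon.  Sites overlapping no exon are
#' dropped and counted in a message.
#'
#' @param path path to a BED file with at least 6 columns
#'   (chrom, start, end, name, score, strand; 0-based half-open).
#' @param exon_table data.frame of terminal exons with columns `exon_id`,
#'   `gene_id`, `chrom`, `start`, `end`, `strand` (same convention).
#' @return A validated `pas_annotation` data.frame.
#' @export
read_pas_atlas <- function(path, exon_table) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines)) stop("no BED records in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6))
    stop("malformed BED line ", which(nf < 6)[1], ": fewer than 6 columns")
  bed <- data.frame(
    chrom  = vapply(fields, `[`, "", 1L),
    start  = suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L))),
    end    = suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L))),
    pas_id = vapply(fields, `[`, "", 4L),
    strand = vapply(fields, `[`, "", 6L),
    stringsAsFactors = FALSE)
  bad <- which(is.na(bed$start) | is.na(bed$end) | !(bed$strand %in% c("+", "-")))
  if (length(bad))
    stop("malformed BED line ", bad[1], ": non-numeric coordinates or bad strand")
  if (anyDuplicated(bed$pas_id)) stop("duplicate PAS names in BED")

  pas_gr <- GenomicRanges::GRanges(
    bed$chrom, IRanges::IRanges(bed$start + 1L, bed$end), strand = bed$strand)
  exon_gr <- GenomicRanges::GRanges(
    exon_table$chrom, IRanges::IRanges(exon_table$start + 1L, exon_table$end),
    strand = exon_table$strand)
  hits <- GenomicRanges::findOverlaps(pas_gr, exon_gr)
  ov <- IRanges::width(IRanges::pintersect(
    pas_gr[S4Vectors::queryHits(hits)], exon_gr[S4Vectors::subjectHits(hits)]))

  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  assign_exon <- rep(NA_integer_, nrow(bed))
  dropped_tie <- integer(0)
  for (i in unique(q)) {
    sel <- which(q == i)
    best <- sel[ov[sel] == max(ov[sel])]
    if (length(best) > 1L) dropped_tie <- c(dropped_tie, i) else
      assign_exon[i] <- s[best]
  }
  if (length(dropped_tie))
    warning(length(dropped_tie),
            " PAS overlapped >=2 exons with equal overlap and were dropped")
  n_unassigned <- sum(is.na(assign_exon)) - length(dropped_tie)
  if (n_unassigned > 0)
    message(n_unassigned, " PAS overlapped no terminal exon and were dropped")

  keep <- !is.na(assign_exon)
  if (!any(keep)) stop("no PAS could be assigned to a terminal exon")
  out <- data.frame(
    pas_id  = bed$pas_id[keep],
    exon_id = exon_table$exon_id[assign_exon[keep]],
    gene_id = exon_table$gene_id[assign_exon[keep]],
    chrom   = bed$chrom[keep],
    start   = bed$start[keep],
    end     = bed$end[keep],
    strand  = bed$strand[keep],
    stringsAsFactors = FALSE)
  validate_pas_annotation(assign_pas_ranks(out))
}

#' Read a labeled numeric matrix from TSV
#'
#' First column holds row identifiers, the header row sample identifiers.
#'
#' @param path TSV file path.
#' @param type "numeric" or "count"; counts must be non-negative integers.
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path, type = c("numeric", "count")) {
  type <- match.arg(type)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("no rows in ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate row ids in ", path)
  if (anyDuplicated(names(df)[-1])) stop("duplicate sample ids in ", path)
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      if (anyNA(conv) && !anyNA(v))
        stop("non-numeric cell at row '", ids[which(is.na(conv))[1]],
             "', column '", names(vals)[j], "'")
      vals[[j]] <- conv
    }
  }
  m <- as.matrix(vals)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (type == "count") {
    if (any(m < 0, na.rm = TRUE)) stop("negative value in count matrix")
    if (any(m != round(m), na.rm = TRUE)) stop("non-integer value in count matrix")
  }
  m
}

#' Write a labeled matrix to TSV
#'
#' Inverse of [read_matrix()]; integer matrices round-trip bit-identically.
#'
#' @param m matrix with dimnames.
#' @param path output path.
#' @param id_col name for the row-identifier column.
#' @export
write_matrix <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a PAS count matrix container
#'
#' Bundles raw read counts supporting each PAS with the site annotation and
#' per-sample library sizes.  Library sizes default to column sums.
#'
#' @param counts non-negative integer matrix, PAS x samples; rownames must
#'   match `annotations$pas_id`.
#' @param annotations `pas_annotation` data.frame.
#' @param library_size optional positive numeric, one per sample.
#' @return list of class `pas_count_matrix`.
#' @export
pas_count_matrix <- function(counts, annotations, library_size = NULL) {
  if (!setequal(rownames(counts), annotations$pas_id))
    stop("count rownames must match annotation pas_ids")
  counts <- counts[annotations$pas_id, , drop = FALSE]
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(library_size)) library_size <- colSums(counts)
  if (length(library_size) != ncol(counts) || any(library_size <= 0))
    stop("library_size must be positive, one per sample")
  names(library_size) <- colnames(counts)
  structure(list(counts = counts, annotations = annotations,
                 samples = colnames(counts), library_size = library_size),
            class = "pas_count_matrix")
}

#' Read a clinical table (survival endpoint, purity, subtype)
#' @param path TSV with columns sample_id, time, event and optionally
#'   purity, subtype.
#' @return validated data.frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "time", "event") %in% names(df)))
  if (any(df$time < 0)) stop("time must be non-negative")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1")
  if ("purity" %in% names(df)) {
    ok <- is.na(df$purity) | (df$purity >= 0 & df$purity <= 1)
    if (!all(ok)) stop("purity must lie in [0,1] when present")
  }
  df
}

#' Read a CLIP evidence table of (rbp_id, exon_id) binding footprints
#' @param path TSV with columns rbp_id, exon_id.
#' @return data.frame without duplicate rows.
#' @export
read_clip <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("rbp_id", "exon_id") %in% names(df)))
  if (anyDuplicated(df[c("rbp_id", "exon_id")]))
    stop("duplicate (rbp_id, exon_id) rows")
  df
}

#' Read a perturbation-panel design table
#'
#' Validates that every experiment has at least one control and one depleted
#' sample and a single target RBP.
#'
#' @param path TSV with columns experiment_id, cell_line, target_rbp,
#'   sample_id, arm, replicate.
#' @return validated data.frame.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("experiment_id", "cell_line", "target_rbp",
                  "sample_id", "arm", "replicate") %in% names(df)))
  if (!all(df$arm %in% c("control", "depleted"))) stop("arm must be control/depleted")
  for (ex in split(df, df$experiment_id)) {
    if (length(unique(ex$target_rbp)) != 1L)
      stop("experiment ", ex$experiment_id[1], ": multiple target RBPs")
    if (!all(c("control", "depleted") %in% ex$arm))
      stop("experiment ", ex$experiment_id[1], ": needs both arms")
  }
  df
}
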