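#' Raw barcode counts with read accounting
#'
#' @param counts Named integer vector (barcode sequence -> read count).
#' @param n_total Total reads entering the pipeline (including any removed by
#'   an upstream quality filter).
#' @param n_filtered Reads removed by quality filtering.
#' @param n_unextractable Reads in which no barcode could be located.
#' @return An object of class `raw_barcode_counts`. Invariant:
#'   `sum(counts) + n_filtered + n_unextractable == n_total`.
#' @export
raw_barcode_counts <- function(counts, n_total = sum(counts),
                               n_filtered = 0L, n_unextractable = 0L) {
  if (length(counts)) {
    counts <- counts[order(-counts, names(counts))]
  } else {
    counts <- stats::setNames(integer(0), character(0))
  }
  storage.mode(counts) <- "integer"
  if (sum(counts) + n_filtered + n_unextractable != n_total)
    stop("read accounting inconsistent: counts + filtered + unextractable != total",
         call. = FALSE)
  structure(list(counts = counts, n_total = as.integer(n_total),
                 n_filtered = as.integer(n_filtered),
                 n_unextractable = as.integer(n_unextractable)),
            class = "raw_barcode_counts")
}

#' @export
print.raw_barcode_counts <- function(x, ...) {
  cat(sprintf(
    "Barcode counts: %d distinct barcodes, %d reads (%d filtered, %d unextractable of %d total)\n",
    length(x$counts), sum(x$counts), x$n_filtered, x$n_unextractable, x$n_total))
  invisible(x)
}

#' Filter reads by mean Phred score
#'
#' Retains reads whose mean Phred score over the barcode-bearing region is
#' strictly greater than `q_min`. The region defaults to the nominal barcode
#' position implied by `pattern` (immediately after the 5' flank); with
#' `pattern = NULL` the whole read is used. A mean-based criterion is used
#' because a per-base minimum would discard most real reads at practical
#' error rates.
#'
#' @param rs A [read_set()].
#' @param q_min Phred threshold (default 30); reads with mean Phred
#'   `> q_min` are kept.
#' @param pattern Optional [barcode_pattern()] locating the barcode region.
#' @return The filtered [read_set()]; attribute `n_filtered` accumulates the
#'   number of removed reads.
#' @export
quality_filter <- function(rs, q_min = 30, pattern = barcode_pattern()) {
  stopifnot(inherits(rs, "read_set"))
  if (q_min < 0 || q_min > 41)
    stop("`q_min` must be in [0, 41]", call. = FALSE)
  if (length(rs) == 0) return(rs)
  qm <- .qual_matrix(rs)
  if (!is.null(pattern)) {
    from <- nchar(pattern$flank5) + 1L
    to <- min(nchar(pattern$flank5) + pattern$length, ncol(qm))
    if (from > ncol(qm))
      stop("reads are shorter than the 5' flank; no barcode region", call. = FALSE)
    qm <- qm[, from:to, drop = FALSE]
  }
  keep <- rowMeans(qm) > q_min
  out <- read_set(rs$seq[keep], rs$qual[keep], rs$id[keep],
                  source = attr(rs, "source"),
                  n_filtered = attr(rs, "n_filtered") + sum(!keep))
  for (a in c("true_counts"))
    if (!is.null(attr(rs, a))) attr(out, a) <- attr(rs, a)
  if (!is.null(attr(rs, "true_clone")))
    attr(out, "true_clone") <- attr(rs, "true_clone")[keep]
  out
}

#' Extract barcodes from reads by flank anchoring
#'
#' Locates the 5' flank in each read (allowing up to `max_flank_mismatch`
#' mismatches; the leftmost admissible position is used) and takes the
#' following `pattern$length` bases as the barcode. Reads with no locatable
#' flank, with a barcode running past the read end, or with a barcode
#' violating the pattern's fixed positions are counted as unextractable
#' rather than raising an error.
#'
#' @param rs A [read_set()].
#' @param pattern A [barcode_pattern()].
#' @param max_flank_mismatch Mismatches tolerated in the 5' flank (default 2).
#' @return A [raw_barcode_counts()].
#' @export
extract_barcodes <- function(rs, pattern = barcode_pattern(),
                             max_flank_mismatch = 2L) {
  stopifnot(inherits(rs, "read_set"), inherits(pattern, "barcode_pattern"))
  if (max_flank_mismatch < 0)
    stop("`max_flank_mismatch` must be >= 0", call. = FALSE)
  n_filt <- attr(rs, "n_filtered")
  if (length(rs) == 0)
    return(raw_barcode_counts(stats::setNames(integer(0), character(0)),
                              n_total = n_filt, n_filtered = n_filt))
  hits <- Biostrings::vmatchPattern(pattern$flank5, rs$seq,
                                    max.mismatch = max_flank_mismatch)
  starts <- Biostrings::startIndex(hits)
  first <- vapply(starts, function(s) if (length(s)) min(s) else NA_integer_,
                  integer(1))
  seqs <- as.character(rs$seq)
  bc_from <- first + nchar(pattern$flank5)
  bc_to <- bc_from + pattern$length - 1L
  ok <- !is.na(first) & bc_to <= nchar(seqs)
  barcode <- rep(NA_character_, length(seqs))
  barcode[ok] <- substr(seqs[ok], bc_from[ok], bc_to[ok])
  barcode[ok][!matches_pattern(barcode[ok], pattern)] <- NA_character_
  tab <- table(barcode, useNA = "no")
  counts <- stats::setNames(as.integer(tab), names(tab))
  raw_barcode_counts(counts,
                     n_total = length(seqs) + n_filt,
                     n_filtered = n_filt,
                     n_unextractable = sum(is.na(barcode)))
}

# Hamming distances between one sequence (int codes) and columns of a matrix.
.hamming_to <- function(code, mat) {
  if (ncol(mat) == 0) return(integer(0))
  .colSums(mat != code, nrow(mat), ncol(mat))
}

#' Error-correct barcode counts by greedy Hamming clustering
#'
#' Merges likely sequencing-error barcodes into their true parents. Barcodes
#' are ranked by descending count (ties broken lexicographically) and scanned
#' in order: a barcode within Hamming distance `max_dist` of an
#' already-accepted parent whose (accumulated) count is at least `min_ratio`
#' times its own is absorbed into that parent; otherwise it is accepted as a
#' new parent. When several parents qualify, the nearest wins, then the
#' higher count, then the lexicographically smaller sequence. The scan is
#' repeated until no merge occurs, so the operation is idempotent, and the
#' total read count is conserved exactly.
#'
#' @param raw A [raw_barcode_counts()].
#' @param max_dist Hamming radius for merging (default 4, suited to 32-mers).
#' @param min_ratio Minimum parent/child count ratio (default 10).
#' @return A [raw_barcode_counts()] with corrected counts; attribute
#'   `n_merged` records how many barcode sequences were absorbed.
#' @export
error_correct <- function(raw, max_dist = 4L, min_ratio = 10) {
  stopifnot(inherits(raw, "raw_barcode_counts"))
  if (max_dist < 0) stop("`max_dist` must be >= 0", call. = FALSE)
  if (min_ratio < 1) stop("`min_ratio` must be >= 1", call. = FALSE)
  counts <- raw$counts
  if (length(counts) <= 1L || max_dist == 0L) {
    out <- raw_barcode_counts(counts, raw$n_total, raw$n_filtered,
                              raw$n_unextractable)
    attr(out, "n_merged") <- 0L
    return(out)
  }
  if (length(unique(nchar(names(counts)))) != 1L)
    stop("barcodes of unequal length cannot be error-corrected", call. = FALSE)
  bc <- names(counts)
  L <- nchar(bc[1])
  codes <- matrix(utf8ToInt(paste(bc, collapse = "")), nrow = L)
  cnt <- as.numeric(counts)
  n_merged_total <- 0L
  repeat {
    alive <- which(cnt > 0)
    ord <- alive[order(-cnt[alive], bc[alive])]
    accepted <- integer(0)
    merged <- FALSE
    for (i in ord) {
      if (length(accepted)) {
        d <- .hamming_to(codes[, i], codes[, accepted, drop = FALSE])
        cand <- which(d <= max_dist & cnt[accepted] / cnt[i] >= min_ratio)
        if (length(cand)) {
          # tie-break: nearest, then higher accumulated count, then lexicographic
          cand <- cand[order(d[cand], -cnt[accepted[cand]], bc[accepted[cand]])]
          p <- accepted[cand[1]]
          cnt[p] <- cnt[p] + cnt[i]
          cnt[i] <- 0
          merged <- TRUE
          n_merged_total <- n_merged_total + 1L
          next
        }
      }
      accepted <- c(accepted, i)
    }
    if (!merged) break
  }
  keep <- cnt > 0
  out <- raw_barcode_counts(stats::setNames(as.integer(cnt[keep]), bc[keep]),
                            raw$n_total, raw$n_filtered, raw$n_unextractable)
  attr(out, "n_merged") <- n_merged_total
  out
}

#' Overlap between observed barcodes and a reference library
#'
#' @param x A [raw_barcode_counts()], or a character vector of barcode
#'   sequences.
#' @param library A [generate_barcode_library()] result, or a character
#'   vector of reference sequences.
#' @return An object of class `overlap_stats` with fields
#'   `n_sample_barcodes`, `n_in_library` and `fraction` (a percentage;
#'   printed to one decimal).
#' @examples
#' ov <- library_overlap(c("AAAA", "CCCC", "GGGG"), c("AAAA", "CCCC", "TTTT"))
#' ov$fraction # 66.67
#' @export
library_overlap <- function(x, library) {
  bcs <- if (inherits(x, "raw_barcode_counts")) names(x$counts) else as.character(x)
  ref <- if (inherits(library, "barcode_library")) library$sequences
         else as.character(library)
  if (length(bcs) == 0)
    stop("overlap is undefined for an empty sample barcode set", call. = FALSE)
  n_in <- sum(bcs %in% ref)
  structure(list(n_sample_barcodes = length(bcs), n_in_library = n_in,
                 fraction = 100 * n_in / length(bcs)),
            class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf("Library overlap: %d of %d sample barcodes in library (%.1f%%)\n",
              x$n_in_library, x$n_sample_barcodes, x$fraction))
  invisible(x)
}

#' Build a multi-sample clone count table
#'
#' Takes per-sample corrected counts and assembles the union of barcodes into
#' a clones x samples matrix (missing entries zero-filled).
#'
#' @param samples Named list of per-sample counts: each element a
#'   [raw_barcode_counts()] or a named integer vector. Names are sample ids
#'   and must be unique.
#' @param metadata Optional data frame of per-sample annotation (e.g. organ,
#'   day, animal) with one row per sample, matched by a `sample_id` column or
#'   by position.
#' @return An object of class `clone_count_table`: list with `counts`
#'   (integer matrix, barcodes as rows, samples as columns) and `metadata`.
#' @export
build_clone_table <- function(samples, metadata = NULL) {
  if (length(samples) == 0) {
    return(structure(list(counts = matrix(integer(0), 0, 0,
                                          dimnames = list(NULL, NULL)),
                          metadata = data.frame(sample_id = character(0))),
                     class = "clone_count_table"))
  }
  ids <- names(samples)
  if (is.null(ids) || any(ids == ""))
    stop("`samples` must be a named list (names are sample ids)", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate sample id: ", ids[duplicated(ids)][1], call. = FALSE)
  vecs <- lapply(samples, function(s) {
    if (inherits(s, "raw_barcode_counts")) s$counts else s
  })
  all_bc <- sort(unique(unlist(lapply(vecs, names))))
  m <- matrix(0L, nrow = length(all_bc), ncol = length(ids),
              dimnames = list(all_bc, ids))
  for (j in seq_along(vecs)) {
    v <- vecs[[j]]
    if (any(v < 0)) stop("counts must be non-negative", call. = FALSE)
    m[names(v), j] <- as.integer(v)
  }
  m <- m[rowSums(m) > 0, , drop = FALSE] # no all-zero clone rows
  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  } else {
    metadata <- as.data.frame(metadata)
    if (!"sample_id" %in% names(metadata)) {
      if (nrow(metadata) != length(ids))
        stop("metadata must have one row per sample", call. = FALSE)
      metadata <- cbind(sample_id = ids, metadata)
    } else {
      metadata <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
    }
  }
  structure(list(counts = m, metadata = metadata), class = "clone_count_table")
}

#' @export
print.clone_count_table <- function(x, ...) {
  cat(sprintf("Clone count table: %d clones x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Write / read a clone count table as TSV
#'
#' Barcodes as rows, samples as columns; first column `barcode`.
#'
#' @param x A `clone_count_table`.
#' @param path File path.
#' @export
write_clone_table <- function(x, path) {
  stopifnot(inherits(x, "clone_count_table"))
  df <- data.frame(barcode = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clone_table
#' @export
read_clone_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$barcode
  structure(list(counts = m,
                 metadata = data.frame(sample_id = colnames(m),
                                       stringsAsFactors = FALSE)),
            class = "clone_count_table")
}

#' Per-sample QC summary as JSON
#'
#' @param raw A [raw_barcode_counts()].
#' @param path Output JSON path.
#' @export
write_qc_json <- function(raw, path) {
  stopifnot(inherits(raw, "raw_barcode_counts"))
  jsonlite::write_json(
    list(n_total = raw$n_total, n_filtered = raw$n_filtered,
         n_unextractable = raw$n_unextractable,
         n_assigned = sum(raw$counts), n_barcodes = length(raw$counts)),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Run the full quantification pipeline on a read set
#'
#' Convenience wrapper: [quality_filter()] then [extract_barcodes()] then
#' [error_correct()].
#'
#' @param rs A [read_set()].
#' @param pattern A [barcode_pattern()].
#' @param q_min Phred threshold (see [quality_filter()]).
#' @param max_flank_mismatch See [extract_barcodes()].
#' @param max_dist,min_ratio See [error_correct()].
#' @return A corrected [raw_barcode_counts()].
#' @export
quantify_reads <- function(rs, pattern = barcode_pattern(), q_min = 30,
                           max_flank_mismatch = 2L, max_dist = 4L,
                           min_ratio = 10) {
  rs <- quality_filter(rs, q_min = q_min, pattern = pattern)
  raw <- extract_barcodes(rs, pattern, max_flank_mismatch = max_flank_mismatch)
  error_correct(raw, max_dist = max_dist, min_ratio = min_ratio)
}
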