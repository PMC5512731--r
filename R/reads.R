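#' Sequencing read error model
#'
#' Parameters of the synthetic amplicon sequencer: single-end read length,
#' i.i.d. per-base substitution probability, and a per-position Phred quality
#' profile (Gaussian around a mean, clipped to `[2, 41]`, Sanger +33
#' encoding). Substitutions and quality strings are drawn independently: the
#' qualities exist so that Phred-based filtering is exercisable, not as a
#' generative error model.
#'
#' @param read_length Read length in bp (default 83, MiSeq single-end).
#' @param substitution_rate Per-base substitution probability in `[0, 1]`.
#' @param quality_mean,quality_sd Mean and dispersion of the per-position
#'   Phred scores (defaults 37 and 3). `quality_mean` may be a scalar or a
#'   vector of length `read_length`.
#' @param phred_offset ASCII offset (33, Sanger).
#' @return An object of class `read_error_model`.
#' @export
read_error_model <- function(read_length = 83L, substitution_rate = 0.003,
                             quality_mean = 37, quality_sd = 3,
                             phred_offset = 33L) {
  read_length <- as.integer(read_length)
  if (read_length < 1L) stop("`read_length` must be positive", call. = FALSE)
  if (substitution_rate < 0 || substitution_rate > 1)
    stop("`substitution_rate` must be in [0, 1]", call. = FALSE)
  if (!length(quality_mean) %in% c(1L, read_length))
    stop("`quality_mean` must be scalar or one value per position", call. = FALSE)
  structure(list(read_length = read_length,
                 substitution_rate = substitution_rate,
                 quality_mean = rep_len(quality_mean, read_length),
                 quality_sd = quality_sd, phred_offset = as.integer(phred_offset)),
            class = "read_error_model")
}

#' Container for sequencing reads with qualities
#'
#' @param seq A `Biostrings::DNAStringSet` (or character vector) of read
#'   sequences.
#' @param qual A `Biostrings::PhredQuality` (or character vector of Phred+33
#'   strings) of matching lengths.
#' @param id Read identifiers.
#' @param source Origin (file name or `"simulated"`).
#' @param n_filtered Reads removed upstream of this set (carried so that
#'   extraction accounting can reconstruct the original total).
#' @return An object of class `read_set` with fields `seq`, `qual`, `id`.
#' @export
read_set <- function(seq, qual, id = NULL, source = NA_character_,
                     n_filtered = 0L) {
  if (is.character(seq)) seq <- Biostrings::DNAStringSet(seq)
  if (is.character(qual)) qual <- Biostrings::PhredQuality(qual)
  if (length(seq) != length(qual))
    stop("`seq` and `qual` must have equal length", call. = FALSE)
  if (!all(Biostrings::width(seq) == Biostrings::width(qual)))
    stop("sequence and quality lengths differ within a record", call. = FALSE)
  if (is.null(id)) id <- sprintf("read_%d", seq_along(seq))
  structure(list(seq = seq, qual = qual, id = as.character(id)),
            class = "read_set", source = source, n_filtered = as.integer(n_filtered))
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("Read set: %d reads", length(x$seq)))
  src <- attr(x, "source")
  if (!is.na(src)) cat(sprintf(" from %s", src))
  nf <- attr(x, "n_filtered")
  if (nf > 0) cat(sprintf(" (%d filtered upstream)", nf))
  cat("\n")
  invisible(x)
}

#' @export
length.read_set <- function(x) length(x$seq)

# Per-read integer Phred scores as a matrix (requires equal read lengths).
.qual_matrix <- function(rs) {
  w <- Biostrings::width(rs$qual)
  if (length(w) == 0) return(matrix(integer(0), nrow = 0, ncol = 0))
  if (length(unique(w)) != 1L)
    stop("reads have unequal lengths; no rectangular quality matrix", call. = FALSE)
  matrix(unlist(methods::as(rs$qual, "IntegerList"), use.names = FALSE),
         nrow = length(w), byrow = TRUE)
}

#' Simulate error-bearing amplicon reads from a clone population
#'
#' Draws `depth` reads multinomially over clone abundances. Each read is the
#' 5' flank + barcode + 3' flank construct truncated to the model's read
#' length, with i.i.d. per-base substitutions and a Phred string drawn from
#' the quality profile.
#'
#' @param pop A [clone_population()] (abundances are normalized).
#' @param depth Number of reads.
#' @param model A [read_error_model()].
#' @param pattern The [barcode_pattern()] defining the flanks.
#' @param seed Integer seed; identical seeds give byte-identical FASTQ output.
#' @return A [read_set()]; attribute `true_counts` holds the multinomial
#'   draw (named by clone id) for provenance checks.
#' @export
simulate_reads <- function(pop, depth, model = read_error_model(),
                           pattern = barcode_pattern(), seed = 1L) {
  stopifnot(inherits(pop, "clone_population"),
            inherits(model, "read_error_model"),
            inherits(pattern, "barcode_pattern"))
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 0) stop("`depth` must be >= 0", call. = FALSE)
  if (nrow(pop) == 0 && depth > 0)
    stop("cannot draw reads from an empty population", call. = FALSE)
  L <- model$read_length
  construct <- paste0(pattern$flank5, pop$barcode, pattern$flank3)
  if (any(nchar(construct) < L))
    stop(sprintf(
      "read_length %d exceeds the %d-nt flank5+barcode+flank3 construct", L,
      min(nchar(construct))), call. = FALSE)
  set.seed(seed)
  if (depth == 0) {
    rs <- read_set(character(0), character(0), character(0), source = "simulated")
    attr(rs, "true_counts") <- stats::setNames(integer(nrow(pop)), pop$clone_id)
    return(rs)
  }
  counts <- as.integer(stats::rmultinom(1, depth, pop$abundance))
  reads <- substr(rep.int(construct, counts), 1L, L)

  # substitutions: choose per-read error counts, then positions and bases
  n_err <- stats::rbinom(depth, L, model$substitution_rate)
  which_err <- which(n_err > 0L)
  if (length(which_err)) {
    pos <- lapply(n_err[which_err], sample.int, n = L)
    m <- matrix(unlist(strsplit(reads[which_err], "", fixed = TRUE)),
                ncol = L, byrow = TRUE)
    ri <- rep.int(seq_along(which_err), n_err[which_err])
    ci <- unlist(pos, use.names = FALSE)
    old <- m[cbind(ri, ci)]
    # substitute uniformly among the three other bases
    bases <- c("A", "C", "G", "T")
    shift <- sample.int(3L, length(old), replace = TRUE)
    m[cbind(ri, ci)] <- bases[(match(old, bases) - 1L + shift) %% 4L + 1L]
    reads[which_err] <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }

  # qualities: Gaussian per position, clipped to [2, 41]
  q <- matrix(stats::rnorm(depth * L,
                           mean = rep(model$quality_mean, each = depth),
                           sd = model$quality_sd), nrow = depth)
  q <- pmin(pmax(round(q), 2L), 41L)
  qchar <- matrix(strsplit(intToUtf8(as.integer(t(q)) + model$phred_offset),
                           "", fixed = TRUE)[[1]], ncol = L, byrow = TRUE)
  quals <- do.call(paste0, as.data.frame(qchar, stringsAsFactors = FALSE))

  rs <- read_set(reads, quals, sprintf("read_%d", seq_len(depth)),
                 source = "simulated")
  attr(rs, "true_counts") <- stats::setNames(counts, pop$clone_id)
  attr(rs, "true_clone") <- rep.int(pop$clone_id, counts)
  rs
}

#' Write a read set as FASTQ (Sanger Phred+33)
#'
#' @param rs A [read_set()].
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(rs, path) {
  stopifnot(inherits(rs, "read_set"))
  seq <- rs$seq
  names(seq) <- rs$id
  Biostrings::writeXStringSet(seq, path, format = "fastq",
                              qualities = methods::as(rs$qual, "BStringSet"),
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Load a FASTQ file into a read set
#'
#' Reads Sanger Phred+33 FASTQ (plain or gzip). Records are validated
#' structurally; a truncated or malformed record raises a parse error naming
#' the offending record index.
#'
#' @param path FASTQ file path.
#' @return A [read_set()].
#' @export
load_reads <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop(sprintf("FASTQ parse error: truncated record %d in %s",
                 length(lines) %/% 4L + 1L, path), call. = FALSE)
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(read_set(character(0), character(0), character(0), source = path))
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  quals <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad))
    stop(sprintf("FASTQ parse error: malformed record %d in %s", bad[1], path),
         call. = FALSE)
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop(sprintf(
      "FASTQ parse error: record %d has sequence/quality length mismatch",
      bad[1]), call. = FALSE)
  read_set(seqs, quals, sub("^@", "", sub("\\s.*$", "", hdr)), source = path)
}
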