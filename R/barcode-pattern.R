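#' Define a barcode cassette layout
#'
#' Describes the architecture of a degenerate DNA barcode as carried inside an
#' amplicon read: its total length, which positions are free to vary (wobble),
#' which positions are fixed to a given base, and the constant flanking
#' adapter sequences that anchor the cassette within a read. The default is a
#' fully degenerate 32-mer bracketed by two constant 20-nt flanks, which keeps
#' the downstream pipeline correct for any concrete cassette design; specific
#' fixed-position layouts can be supplied via `fixed`.
#'
#' @param length Integer, barcode length in nucleotides (default 32).
#' @param fixed Named character vector mapping positions (names, coercible to
#'   integer) to single bases in `A/C/G/T`, e.g. `c("5" = "T")`. Positions not
#'   listed are wobble positions.
#' @param flank5,flank3 Constant sequences immediately 5' and 3' of the
#'   barcode. Must be non-empty and contain only `A/C/G/T`.
#' @return An object of class `barcode_pattern` with fields `length`,
#'   `wobble` (integer positions), `fixed` (named character vector), `flank5`
#'   and `flank3`.
#' @examples
#' p <- barcode_pattern()
#' pattern_capacity(barcode_pattern(length = 4, fixed = c("1" = "A", "2" = "C")))
#' @export
barcode_pattern <- function(length = 32L,
                            fixed = character(0),
                            flank5 = "ACTGACGTAGCATCGATCGA",
                            flank3 = "TGACCTAGCTAGGATCCAGTGGTCTGAAGCTCAACGTTAG") {
  length <- as.integer(length)
  if (is.na(length) || length < 1L)
    stop("barcode `length` must be a positive integer", call. = FALSE)
  for (fl in list(flank5 = flank5, flank3 = flank3)) {
    if (!is.character(fl) || length(fl) != 1L || nchar(fl) == 0L)
      stop("flanks must be non-empty strings", call. = FALSE)
    if (grepl("[^ACGT]", fl))
      stop("flanks must contain only A/C/G/T (no ambiguity codes)", call. = FALSE)
  }
  if (length(fixed)) {
    pos <- suppressWarnings(as.integer(names(fixed)))
    if (anyNA(pos) || any(pos < 1L) || any(pos > length) || anyDuplicated(pos))
      stop("`fixed` names must be distinct positions in 1..length", call. = FALSE)
    if (!all(fixed %in% c("A", "C", "G", "T")))
      stop("`fixed` bases must be one of A/C/G/T", call. = FALSE)
    fixed <- stats::setNames(as.character(fixed), pos)
    fixed <- fixed[order(pos)]
  } else {
    fixed <- character(0)
  }
  wobble <- setdiff(seq_len(length), as.integer(names(fixed)))
  structure(
    list(length = length, wobble = wobble, fixed = fixed,
         flank5 = flank5, flank3 = flank3),
    class = "barcode_pattern"
  )
}

#' @export
print.barcode_pattern <- function(x, ...) {
  cat(sprintf("Barcode pattern: %d nt, %d wobble / %d fixed positions\n",
              x$length, length(x$wobble), length(x$fixed)))
  cat(sprintf("  5' flank: %s\n  3' flank: %s\n", x$flank5, x$flank3))
  cat(sprintf("  capacity: %s distinct sequences\n",
              format(pattern_capacity(x), big.mark = ",")))
  invisible(x)
}

#' Number of distinct sequences a pattern admits
#'
#' @param pattern A [barcode_pattern()].
#' @return `4^n_wobble` as a double (may be very large; exact for small
#'   patterns, approximate beyond 2^53).
#' @export
pattern_capacity <- function(pattern) {
  stopifnot(inherits(pattern, "barcode_pattern"))
  4^length(pattern$wobble)
}

#' Test whether sequences match a pattern
#'
#' A sequence matches when it has the pattern's length, contains only
#' `A/C/G/T`, and agrees with every fixed position.
#'
#' @param sequences Character vector of sequences.
#' @inheritParams pattern_capacity
#' @return Logical vector.
#' @export
matches_pattern <- function(sequences, pattern) {
  stopifnot(inherits(pattern, "barcode_pattern"))
  ok <- nchar(sequences) == pattern$length & !grepl("[^ACGT]", sequences)
  if (length(pattern$fixed)) {
    pos <- as.integer(names(pattern$fixed))
    for (i in seq_along(pos)) {
      ok <- ok & substr(sequences, pos[i], pos[i]) == pattern$fixed[[i]]
    }
  }
  ok
}

# Template with fixed bases filled in and NA at wobble positions.
.pattern_template <- function(pattern) {
  tmpl <- rep(NA_character_, pattern$length)
  if (length(pattern$fixed))
    tmpl[as.integer(names(pattern$fixed))] <- pattern$fixed
  tmpl
}

# n random sequences matching `pattern` (duplicates possible).
.random_barcodes <- function(n, pattern) {
  if (n == 0L) return(character(0))
  tmpl <- .pattern_template(pattern)
  cols <- vector("list", pattern$length)
  for (j in seq_len(pattern$length)) {
    cols[[j]] <- if (is.na(tmpl[j])) {
      sample(c("A", "C", "G", "T"), n, replace = TRUE)
    } else {
      rep(tmpl[j], n)
    }
  }
  do.call(paste0, cols)
}

# Full enumeration of a small pattern (used when capacity is modest).
.enumerate_barcodes <- function(pattern) {
  tmpl <- .pattern_template(pattern)
  grid <- expand.grid(rep(list(c("A", "C", "G", "T")), length(pattern$wobble)),
                      stringsAsFactors = FALSE)
  out <- character(nrow(grid))
  mat <- matrix(rep(tmpl, each = nrow(grid)), nrow = nrow(grid))
  mat[, pattern$wobble] <- as.matrix(grid)
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

#' Generate a barcode library
#'
#' Draws `n_barcodes` distinct sequences matching a pattern, emulating a
#' plasmid barcode library (tens of thousands of distinct cassettes).
#'
#' @param n_barcodes Number of distinct barcodes to generate.
#' @param pattern A [barcode_pattern()].
#' @param seed Integer seed; the same seed reproduces the same library.
#' @return An object of class `barcode_library`: list with `pattern` and
#'   `sequences` (character vector, pairwise distinct, each matching
#'   `pattern`).
#' @examples
#' lib <- generate_barcode_library(1000, barcode_pattern(), seed = 1)
#' length(lib$sequences)
#' @export
generate_barcode_library <- function(n_barcodes, pattern = barcode_pattern(),
                                     seed = 1L) {
  stopifnot(inherits(pattern, "barcode_pattern"))
  n_barcodes <- as.numeric(n_barcodes)
  if (is.na(n_barcodes) || n_barcodes < 0)
    stop("`n_barcodes` must be a non-negative count", call. = FALSE)
  cap <- pattern_capacity(pattern)
  if (n_barcodes > cap)
    stop(sprintf(
      "pattern capacity exceeded: requested %s barcodes but only %s are possible",
      format(n_barcodes, big.mark = ","), format(cap, big.mark = ",")),
      call. = FALSE)
  n_barcodes <- as.integer(n_barcodes)
  set.seed(seed)
  if (cap <= 65536) {
    seqs <- sample(.enumerate_barcodes(pattern), n_barcodes)
  } else {
    seqs <- unique(.random_barcodes(n_barcodes, pattern))
    while (length(seqs) < n_barcodes) {
      extra <- .random_barcodes(n_barcodes - length(seqs), pattern)
      seqs <- unique(c(seqs, extra))
    }
  }
  structure(list(pattern = pattern, sequences = seqs),
            class = "barcode_library")
}

#' @export
print.barcode_library <- function(x, ...) {
  cat(sprintf("Barcode library: %s distinct %d-nt sequences\n",
              format(length(x$sequences), big.mark = ","), x$pattern$length))
  invisible(x)
}
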