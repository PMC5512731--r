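# Shared fixtures and independent oracles used across the suite.

# small pattern: 2 wobble positions -> capacity 16 (enumerable by hand)
tiny_pattern <- function() {
  barcode_pattern(length = 4,
                  fixed = c("1" = "A", "3" = "G"),
                  flank5 = "ACGT", flank3 = "TGCATGCA")
}

# a small but realistic read-simulation setup
small_pop <- function(n_clones = 20, seed = 11) {
  lib <- generate_barcode_library(500, barcode_pattern(), seed = seed)
  simulate_transduction(lib, n_clones, seed = seed + 1)
}

# write a read_set to a temp FASTQ and return the path
temp_fastq <- function(rs, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".fastq", .local_envir = envir)
  write_fastq(rs, path)
  path
}

# Independent brute-force recoding of the error-correction rule: repeated
# count-ranked greedy passes to a fixed point, string-based Hamming
# distances, no matrix shortcuts. Kept deliberately naive.
oracle_error_correct <- function(counts, max_dist, min_ratio) {
  ham <- function(x, y) {
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }
  counts <- counts[order(-counts, names(counts))]
  repeat {
    merged_any <- FALSE
    ord <- names(counts)[order(-counts, names(counts))]
    accepted <- character(0)
    for (b in ord) {
      if (counts[[b]] == 0) next
      cand <- character(0)
      for (p in accepted) {
        if (ham(b, p) <= max_dist && counts[[p]] / counts[[b]] >= min_ratio)
          cand <- c(cand, p)
      }
      if (length(cand)) {
        d <- vapply(cand, ham, numeric(1), x = b)
        cand <- cand[order(d, -counts[cand], cand)]
        counts[[cand[1]]] <- counts[[cand[1]]] + counts[[b]]
        counts[[b]] <- 0
        merged_any <- TRUE
      } else {
        accepted <- c(accepted, b)
      }
    }
    counts <- counts[counts > 0]
    if (!merged_any) break
  }
  counts[order(-counts, names(counts))]
}

# random raw_barcode_counts instance for property tests
random_counts <- function(n, len = 6, max_count = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bcs <- unique(replicate(n, paste(sample(c("A", "C", "G", "T"), len,
                                          replace = TRUE), collapse = "")))
  stats::setNames(as.integer(stats::rpois(length(bcs), max_count / 10) + 1L),
                  bcs)
}

# down-scaled niche model for fast property tests
fast_params <- function(...) {
  model_params(N_bar_A = 300, N_bar_Omega = 300, ...)
}

# calibrated study configuration, loaded once per test run
calibrated_config <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- shipped_config("calibrated")
    cache
  }
})
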