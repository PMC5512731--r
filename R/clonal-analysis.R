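# Resolve one sample column of a clone count table (or accept a bare vector).
.sample_counts <- function(table, sample) {
  if (inherits(table, "clone_count_table")) {
    if (!sample %in% colnames(table$counts))
      stop("unknown sample: ", sample, call. = FALSE)
    return(table$counts[, sample])
  }
  if (is.numeric(table)) return(table)
  stop("`table` must be a clone_count_table or a numeric vector", call. = FALSE)
}

#' Clone richness of a sample
#'
#' Number of clones detected with at least `min_reads` reads.
#'
#' @param table A `clone_count_table` (or a named count vector).
#' @param sample Sample id (ignored for bare vectors).
#' @param min_reads Detection threshold (default 1).
#' @return Integer count. Monotonically non-increasing in `min_reads`.
#' @export
richness <- function(table, sample = NULL, min_reads = 1) {
  x <- .sample_counts(table, sample)
  sum(x >= min_reads)
}

#' Per-clone fractional abundances of a sample
#'
#' @inheritParams richness
#' @return Named numeric vector of fractions summing to 1.
#' @export
abundances <- function(table, sample = NULL) {
  x <- .sample_counts(table, sample)
  tot <- sum(x)
  if (tot <= 0)
    stop("abundances are undefined for a sample with zero total reads",
         call. = FALSE)
  x / tot
}

#' Shannon diversity of a sample
#'
#' `H = -sum(p_i * log(p_i))` in nats over clones with non-zero abundance.
#'
#' @inheritParams richness
#' @return Entropy in nats; `log(k)` for `k` equally abundant clones, 0 for a
#'   single clone.
#' @export
shannon_diversity <- function(table, sample = NULL) {
  p <- abundances(table, sample)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Classify clonal dominance of a (leukemic) sample
#'
#' Declarative outcome call from per-clone abundances: `no_leukemia` when the
#' disease flag is FALSE; `monoclonal` when the top clone holds at least
#' `t_mono` of the reads; `biclonal` when the top two clones jointly hold at
#' least `t_mono` and each holds at least `t_minor`; otherwise `polyclonal`.
#' Input may be counts or fractions; the call is scale-invariant.
#'
#' @param fractions Named non-negative vector of per-clone counts or
#'   fractions.
#' @param t_mono Dominance threshold (default 0.90).
#' @param t_minor Minimum share for each clone of a biclonal pair
#'   (default 0.10).
#' @param leukemia_flag Whether the sample is leukemic at all.
#' @return An object of class `dominance_call`: list with `category` and
#'   `dominant_clones` (data frame `clone`, `fraction`, sorted descending;
#'   the clones supporting the call, empty for `no_leukemia`/`polyclonal`).
#' @export
classify_dominance <- function(fractions, t_mono = 0.90, t_minor = 0.10,
                               leukemia_flag = TRUE) {
  if (t_mono <= 0 || t_mono >= 1 || t_minor <= 0 || t_minor >= 1)
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  if (any(fractions < 0) || anyNA(fractions))
    stop("abundances must be non-negative and finite", call. = FALSE)
  empty <- data.frame(clone = character(0), fraction = numeric(0),
                      stringsAsFactors = FALSE)
  if (!leukemia_flag) {
    return(structure(list(category = "no_leukemia", dominant_clones = empty),
                     class = "dominance_call"))
  }
  tot <- sum(fractions)
  if (tot <= 0)
    stop("cannot classify an all-zero abundance vector", call. = FALSE)
  p <- sort(fractions / tot, decreasing = TRUE)
  if (is.null(names(p))) names(p) <- sprintf("clone_%d", seq_along(p))
  category <- if (p[1] >= t_mono) {
    "monoclonal"
  } else if (length(p) >= 2 && p[1] + p[2] >= t_mono &&
             p[2] >= t_minor) {
    "biclonal"
  } else {
    "polyclonal"
  }
  dom <- switch(category,
                monoclonal = data.frame(clone = names(p)[1], fraction = p[[1]],
                                        stringsAsFactors = FALSE),
                biclonal = data.frame(clone = names(p)[1:2],
                                      fraction = as.numeric(p[1:2]),
                                      stringsAsFactors = FALSE),
                empty)
  structure(list(category = category, dominant_clones = dom,
                 thresholds = c(t_mono = t_mono, t_minor = t_minor)),
            class = "dominance_call")
}

#' @export
print.dominance_call <- function(x, ...) {
  cat(sprintf("Dominance call: %s", x$category))
  if (nrow(x$dominant_clones))
    cat(sprintf(" (%s)", paste(sprintf("%s %.1f%%", x$dominant_clones$clone,
                                       100 * x$dominant_clones$fraction),
                               collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Relative transcript quantification by the delta-delta-Ct method
#'
#' Fold change of a target transcript in a sample relative to a control,
#' each normalized to a reference gene:
#' `fold = 2^-((Ct_ts - Ct_rs) - (Ct_tc - Ct_rc))`.
#'
#' @param ct_target_sample,ct_reference_sample Cycle thresholds of target and
#'   reference gene in the sample of interest.
#' @param ct_target_control,ct_reference_control Cycle thresholds in the
#'   control (calibrator) sample.
#' @return Dimensionless fold change (1 when the normalized Ct difference is
#'   zero).
#' @examples
#' ddct_fold_change(20, 18, 22, 18) # 4: target is 2 cycles earlier in sample
#' @export
ddct_fold_change <- function(ct_target_sample, ct_reference_sample,
                             ct_target_control, ct_reference_control) {
  cts <- c(ct_target_sample, ct_reference_sample,
           ct_target_control, ct_reference_control)
  if (anyNA(cts) || any(!is.finite(cts)))
    stop("all Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_sample - ct_reference_sample) -
    (ct_target_control - ct_reference_control)
  2^(-ddct)
}

#' Per-sample analysis summary
#'
#' Richness, Shannon diversity and dominance call for every sample of a count
#' table, mirroring an organ x clone reporting layout.
#'
#' @param table A `clone_count_table`.
#' @param t_mono,t_minor Dominance thresholds, see [classify_dominance()].
#' @param leukemic Logical vector (recycled) flagging leukemic samples.
#' @return Data frame with one row per sample: `sample_id`, `richness`,
#'   `shannon`, `category`, `dominant_clones` (comma-separated).
#' @export
analyze_samples <- function(table, t_mono = 0.90, t_minor = 0.10,
                            leukemic = TRUE) {
  stopifnot(inherits(table, "clone_count_table"))
  ids <- colnames(table$counts)
  leukemic <- rep_len(leukemic, length(ids))
  rows <- lapply(seq_along(ids), function(j) {
    call <- classify_dominance(table$counts[, j], t_mono, t_minor, leukemic[j])
    data.frame(sample_id = ids[j],
               richness = richness(table, ids[j]),
               shannon = shannon_diversity(table, ids[j]),
               category = call$category,
               dominant_clones = paste(call$dominant_clones$clone,
                                       collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
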