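#' Construct a clone population
#'
#' A clone population records, for one timepoint, the barcoded clones present
#' in a culture or graft: clone id, barcode sequence, class label and relative
#' abundance. Class labels distinguish the anonymous transduced bulk (`bulk`)
#' from individually designated clones (`A`, `B`).
#'
#' @param clone_id Character vector of distinct clone identifiers.
#' @param barcode Character vector of distinct barcode sequences.
#' @param class Class label per clone, one of `"bulk"`, `"A"`, `"B"`.
#' @param abundance Non-negative relative abundances; normalized to sum to 1.
#' @param day Days since transduction (timepoint of this snapshot).
#' @param fitness Optional per-clone selection coefficient used by
#'   [simulate_culture()] (0 = neutral; growth rate is scaled by `1 + fitness`).
#' @return A `clone_population`: data frame with columns `clone_id`,
#'   `barcode`, `class`, `abundance`, `fitness` and attribute `day`.
#' @export
clone_population <- function(clone_id, barcode, class = "bulk",
                             abundance = 1, day = 0, fitness = 0) {
  n <- length(clone_id)
  class <- rep_len(class, n)
  abundance <- rep_len(as.numeric(abundance), n)
  fitness <- rep_len(as.numeric(fitness), n)
  if (length(barcode) != n)
    stop("`clone_id` and `barcode` must have equal length", call. = FALSE)
  if (anyDuplicated(clone_id))
    stop("clone ids must be distinct", call. = FALSE)
  if (anyDuplicated(barcode))
    stop("barcodes must be distinct across clones", call. = FALSE)
  if (!all(class %in% c("bulk", "A", "B")))
    stop("`class` must be one of \"bulk\", \"A\", \"B\"", call. = FALSE)
  if (any(abundance < 0) || anyNA(abundance))
    stop("abundances must be non-negative", call. = FALSE)
  tot <- sum(abundance)
  if (n > 0 && tot > 0) abundance <- abundance / tot
  out <- data.frame(clone_id = as.character(clone_id),
                    barcode = as.character(barcode),
                    class = class, abundance = abundance, fitness = fitness,
                    stringsAsFactors = FALSE)
  attr(out, "day") <- day
  class(out) <- c("clone_population", "data.frame")
  out
}

#' @export
print.clone_population <- function(x, ...) {
  cat(sprintf("Clone population: %d clones at day %s\n",
              nrow(x), format(attr(x, "day"))))
  if (nrow(x)) {
    top <- utils::head(x[order(-x$abundance), c("clone_id", "class", "abundance")], 5)
    top$abundance <- sprintf("%.2f%%", 100 * top$abundance)
    print.data.frame(top, row.names = FALSE)
    if (nrow(x) > 5) cat(sprintf("  ... and %d more clones\n", nrow(x) - 5L))
  }
  invisible(x)
}

#' Simulate retroviral transduction of a cell population
#'
#' Assigns barcodes from a library to newly transduced clones. By default
#' barcodes are sampled without replacement (each clone carries a unique
#' barcode, matching the high-diversity-library assumption); with
#' `replace = TRUE` collisions are possible, which is useful for studying the
#' birthday-problem collision rate of finite libraries.
#'
#' @param library A [generate_barcode_library()] result.
#' @param n_clones Number of transduced clones.
#' @param seed Integer seed.
#' @param replace Sample barcodes with replacement (default `FALSE`).
#' @return A [clone_population()] at day 0 with equal abundances and class
#'   `"bulk"`. With `replace = TRUE`, clones sharing a barcode are collapsed,
#'   so fewer than `n_clones` rows may result; attribute `n_collisions`
#'   records how many draws were lost to collisions.
#' @export
simulate_transduction <- function(library, n_clones, seed = 1L,
                                  replace = FALSE) {
  stopifnot(inherits(library, "barcode_library"))
  n_clones <- as.integer(n_clones)
  if (is.na(n_clones) || n_clones < 0)
    stop("`n_clones` must be a non-negative count", call. = FALSE)
  if (!replace && n_clones > length(library$sequences))
    stop(sprintf(
      "library capacity exceeded: %d clones requested from %d barcodes",
      n_clones, length(library$sequences)), call. = FALSE)
  set.seed(seed)
  bcs <- sample(library$sequences, n_clones, replace = replace)
  n_coll <- 0L
  if (replace) {
    n_coll <- n_clones - length(unique(bcs))
    bcs <- unique(bcs)
  }
  pop <- clone_population(
    clone_id = sprintf("clone_%04d", seq_along(bcs)),
    barcode = bcs,
    abundance = if (length(bcs)) rep(1 / length(bcs), length(bcs)) else numeric(0)
  )
  attr(pop, "n_collisions") <- n_coll
  pop
}

#' Designate named clones within a population
#'
#' Relabels selected clones (e.g. the two leukemia-driving clones) with class
#' `"A"`/`"B"` and optionally sets their abundance and fitness.
#'
#' @param pop A [clone_population()].
#' @param clone_id Clone ids to relabel.
#' @param class New class label(s), recycled.
#' @param abundance Optional new abundances for the designated clones; the
#'   remaining clones are rescaled proportionally so the total stays 1.
#' @param fitness Optional new per-clone selection coefficients.
#' @return The modified `clone_population`.
#' @export
designate_clones <- function(pop, clone_id, class, abundance = NULL,
                             fitness = NULL) {
  stopifnot(inherits(pop, "clone_population"))
  idx <- match(clone_id, pop$clone_id)
  if (anyNA(idx))
    stop("unknown clone id(s): ", paste(clone_id[is.na(idx)], collapse = ", "),
         call. = FALSE)
  pop$class[idx] <- rep_len(class, length(idx))
  if (!is.null(fitness)) pop$fitness[idx] <- rep_len(fitness, length(idx))
  if (!is.null(abundance)) {
    abundance <- rep_len(as.numeric(abundance), length(idx))
    if (any(abundance < 0) || sum(abundance) > 1)
      stop("designated abundances must be non-negative and sum to at most 1",
           call. = FALSE)
    rest <- setdiff(seq_len(nrow(pop)), idx)
    rest_tot <- sum(pop$abundance[rest])
    if (rest_tot > 0) {
      pop$abundance[rest] <- pop$abundance[rest] *
        (1 - sum(abundance)) / rest_tot
    }
    pop$abundance[idx] <- abundance
  }
  pop
}

#' Write / read clone populations as TSV
#'
#' The on-disk format has columns `clone_id`, `barcode`, `class`, `abundance`,
#' `day` (one block per timepoint for trajectories).
#'
#' @param x A `clone_population` or a list of them (trajectory).
#' @param path File path.
#' @return `write_clone_tsv` returns `path` invisibly; `read_clone_tsv`
#'   returns a list of `clone_population` objects, one per day.
#' @export
write_clone_tsv <- function(x, path) {
  if (inherits(x, "clone_population")) x <- list(x)
  rows <- do.call(rbind, lapply(x, function(p) {
    data.frame(clone_id = p$clone_id, barcode = p$barcode, class = p$class,
               abundance = p$abundance, day = attr(p, "day"),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clone_tsv
#' @export
read_clone_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  lapply(split(df, df$day), function(d) {
    clone_population(d$clone_id, d$barcode, d$class, d$abundance,
                     day = d$day[1])
  })
}
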