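#' Construct a model state
#'
#' The full agent population of the niche model: one row per cell with its
#' clone id, class, compartment, attachment affinity and cycle position, plus
#' the cumulative differentiated output per clone.
#'
#' @param cells Data frame with columns `clone_id` (character), `class`
#'   (`host`/`bulk`/`A`/`B`), `compartment` (`"A"`, `"Omega"` or `"pre"` for
#'   not-yet-engrafted transplants), `affinity`, `cycle` (hours within the
#'   cell cycle, `Omega` only) and optionally `window` (hours of engraftment
#'   attempt left, `pre` only).
#' @param t Model time in hours.
#' @param diff_out Named numeric vector: cumulative differentiated output per
#'   clone (zero-filled for clones without output).
#' @param n_lost Transplanted cells lost without engrafting.
#' @return An object of class `model_state`.
#' @export
model_state <- function(cells, t = 0, diff_out = NULL, n_lost = 0L) {
  need <- c("clone_id", "class", "compartment", "affinity", "cycle")
  if (!all(need %in% names(cells)))
    stop("cells need columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (!"window" %in% names(cells)) cells$window <- 0
  if (!all(cells$class %in% CLASS_LEVELS))
    stop("unknown cell class", call. = FALSE)
  if (!all(cells$compartment %in% c("A", "Omega", "pre")))
    stop("compartment must be \"A\", \"Omega\" or \"pre\"", call. = FALSE)
  clones <- unique(c(cells$clone_id, names(diff_out)))
  d <- stats::setNames(numeric(length(clones)), clones)
  if (!is.null(diff_out)) d[names(diff_out)] <- diff_out
  structure(list(cells = cells, t = t, diff_out = d,
                 n_lost = as.integer(n_lost),
                 converged = NA),
            class = "model_state")
}

#' @export
print.model_state <- function(x, ...) {
  cen <- census(x)
  cat(sprintf("Model state at t = %g h (day %.1f): %d cells\n",
              x$t, x$t / 24, nrow(x$cells)))
  print(cen)
  if (!is.na(x$converged))
    cat(sprintf("  steady state: %s\n",
                if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Compartment census of a model state
#'
#' @param state A [model_state()].
#' @return Matrix of cell counts, compartments x classes, plus a
#'   `differentiated` row of cumulative per-class output.
#' @export
census <- function(state) {
  stopifnot(inherits(state, "model_state"))
  cells <- state$cells
  m <- matrix(0, nrow = 3, ncol = length(CLASS_LEVELS),
              dimnames = list(c("A", "Omega", "differentiated"), CLASS_LEVELS))
  if (nrow(cells)) {
    tab <- table(factor(cells$compartment, c("A", "Omega")),
                 factor(cells$class, CLASS_LEVELS))
    m[1:2, ] <- as.matrix(tab)
  }
  cls_of_clone <- .clone_classes(state)
  if (length(state$diff_out))
    m[3, ] <- vapply(CLASS_LEVELS, function(cl)
      sum(state$diff_out[names(cls_of_clone)[cls_of_clone == cl]]), numeric(1))
  m
}

# class label of every clone id known to the state
.clone_classes <- function(state) {
  cells <- state$cells
  known <- stats::setNames(cells$class[!duplicated(cells$clone_id)],
                           cells$clone_id[!duplicated(cells$clone_id)])
  extra <- setdiff(names(state$diff_out), names(known))
  memo <- attr(state, "clone_class_memo")
  if (length(extra)) {
    lab <- if (!is.null(memo)) memo[extra] else rep(NA_character_, length(extra))
    lab[is.na(lab)] <- "host"
    known <- c(known, stats::setNames(lab, extra))
  }
  known
}

#' Initialize a host-only population
#'
#' @param params A [model_params()].
#' @param occupancy Initial niche occupancy as a fraction of
#'   `N_bar_A * pool_scale` (default 0.5).
#' @param omega_fraction Cells additionally placed in the cycling compartment,
#'   as a fraction of the initial niche census.
#' @param seed Integer seed (randomizes initial cycle positions).
#' @return A [model_state()] of host cells (clone id `"host"`).
#' @export
init_host_state <- function(params = model_params(), occupancy = 0.5,
                            omega_fraction = 0.1, seed = 1L) {
  validate_model_params(params)
  set.seed(seed)
  nA <- round(occupancy * params$N_bar_A * params$pool_scale)
  nO <- round(omega_fraction * nA)
  cells <- data.frame(
    clone_id = rep("host", nA + nO),
    class = rep("host", nA + nO),
    compartment = rep(c("A", "Omega"), c(nA, nO)),
    affinity = c(rep(params$a_max, nA),
                 stats::runif(nO, sqrt(params$a_min * params$a_max),
                              params$a_max)),
    cycle = c(rep(0, nA), floor(stats::runif(nO, 0, params$tau_c))),
    window = rep(0, nA + nO),
    stringsAsFactors = FALSE
  )
  model_state(cells, t = 0, diff_out = c(host = 0))
}

#' Advance a model state
#'
#' Runs the stochastic per-step update for a number of steps (or days):
#' affinity regeneration/attenuation, stochastic compartment transitions,
#' division at the end of each cell cycle, differentiation below `a_min`,
#' and engraftment attempts of pre-engraftment cells.
#'
#' @param state A [model_state()].
#' @param params A [model_params()].
#' @param steps Number of time steps; alternatively give `days`.
#' @param days Duration in days (`days * 24 / dt` steps).
#' @param seed Integer seed, or `NULL` to continue the current RNG stream.
#' @param check_every Evaluate the leukemia stopping rule every this many
#'   steps (0, the default, never): the run ends early once leukemic cells
#'   (live plus differentiated output accumulated during this run) reach
#'   `leukemia_threshold` of the total, or once no leukemic cell remains.
#' @param leukemia_threshold Leukemic fraction that stops the run (only used
#'   with `check_every > 0`; negative disables the threshold).
#' @return The advanced [model_state()]; attributes `ledger` (per-step
#'   conservation accounting: before/births/diffs/deaths/lost/after),
#'   `trajectory` (per-step census by compartment and class), `steps_run`
#'   and `crossed` describe the run.
#' @export
run_model <- function(state, params = model_params(), steps = NULL,
                      days = NULL, seed = NULL, check_every = 0L,
                      leukemia_threshold = -1) {
  stopifnot(inherits(state, "model_state"))
  validate_model_params(params)
  if (is.null(steps)) {
    if (is.null(days)) stop("give `steps` or `days`", call. = FALSE)
    steps <- round(days * 24 / params$dt)
  }
  steps <- as.integer(steps)
  if (!is.null(seed)) set.seed(seed)
  cells <- state$cells
  clone_levels <- unique(c(names(state$diff_out), cells$clone_id))
  clone_i <- match(cells$clone_id, clone_levels) - 1L
  cls_i <- match(cells$class, CLASS_LEVELS) - 1L
  comp_i <- match(cells$compartment, c("A", "Omega", "pre")) - 1L
  res <- .ck_run_model(clone_i, cls_i, comp_i,
                       as.numeric(cells$affinity), as.numeric(cells$cycle),
                       as.numeric(cells$window), .par_for_cpp(params),
                       steps, length(clone_levels),
                       as.integer(check_every), leukemia_threshold)
  new_cells <- data.frame(
    clone_id = clone_levels[res$clone + 1L],
    class = CLASS_LEVELS[res$cls + 1L],
    compartment = c("A", "Omega", "pre")[res$comp + 1L],
    affinity = res$aff, cycle = res$cyc, window = res$win,
    stringsAsFactors = FALSE
  )
  diff_out <- state$diff_out
  add <- stats::setNames(res$diff_out, clone_levels)
  miss <- setdiff(clone_levels, names(diff_out))
  if (length(miss)) diff_out[miss] <- 0
  diff_out[clone_levels] <- diff_out[clone_levels] + add
  out <- model_state(new_cells, t = state$t + res$steps_run * params$dt,
                     diff_out = diff_out,
                     n_lost = state$n_lost + res$lost)
  out$converged <- state$converged
  # remember classes of clones whose last live cell has gone
  memo <- stats::setNames(cells$class[!duplicated(cells$clone_id)],
                          cells$clone_id[!duplicated(cells$clone_id)])
  prev <- attr(state, "clone_class_memo")
  if (!is.null(prev)) memo <- c(memo, prev[setdiff(names(prev), names(memo))])
  attr(out, "clone_class_memo") <- memo
  attr(out, "ledger") <- res$ledger
  attr(out, "steps_run") <- res$steps_run
  attr(out, "crossed") <- res$crossed
  traj <- res$traj
  colnames(traj) <- c(paste0("A_", CLASS_LEVELS), paste0("Omega_", CLASS_LEVELS))
  attr(out, "trajectory") <- traj
  attr(out, "engrafted") <- stats::setNames(res$engrafted, clone_levels)
  out
}

#' Evolve a host-only population to homeostasis
#'
#' Runs the model until the coefficient of variation of the niche census over
#' a trailing window falls below `tolerance`, or `max_days` is reached.
#' Non-convergence is flagged on the returned state, not raised.
#'
#' @param params A [model_params()].
#' @param max_days Maximum simulated days (default 120).
#' @param tolerance CV threshold for the trailing `window_days` of daily
#'   `N_A` values (default 0.05).
#' @param window_days Trailing window (default 10 days).
#' @param seed Integer seed.
#' @param occupancy Initial occupancy passed to [init_host_state()].
#' @return A converged (or flagged unconverged) [model_state()]; attribute
#'   `n_a_daily` holds the daily niche census history.
#' @export
run_to_steady_state <- function(params = model_params(), max_days = 120,
                                tolerance = 0.05, window_days = 10,
                                seed = 1L, occupancy = 0.5) {
  validate_model_params(params)
  state <- init_host_state(params, occupancy = occupancy, seed = seed)
  if (nrow(state$cells) == 0) {
    state$converged <- TRUE # nothing can change without cells
    attr(state, "n_a_daily") <- numeric(0)
    return(state)
  }
  n_a <- numeric(0)
  steps_per_day <- round(24 / params$dt)
  for (day in seq_len(max_days)) {
    state <- run_model(state, params, steps = steps_per_day)
    n_a <- c(n_a, sum(state$cells$compartment == "A"))
    if (day >= window_days) {
      w <- utils::tail(n_a, window_days)
      if (mean(w) > 0 && stats::sd(w) / mean(w) < tolerance) {
        state$converged <- TRUE
        attr(state, "n_a_daily") <- n_a
        return(state)
      }
    }
  }
  state$converged <- FALSE
  attr(state, "n_a_daily") <- n_a
  state
}
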