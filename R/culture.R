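#' Build an in vitro culture schedule
#'
#' A schedule is a table of dated events applied to a growing culture:
#' `passage` events resample the culture down to a bottleneck of `size` cells
#' (multinomial over clones), and `sort` events remove each clone
#' independently with probability `fraction` (emulating the loss of
#' vector-positive but reporter-negative clones at a FACS sort).
#'
#' @param passage_days Days at which the culture is passaged.
#' @param bottleneck Cells retained at each passage. The default (1900) is an
#'   effective bottleneck: it absorbs all stochastic loss processes of routine
#'   culture and is sized so that a 158-clone culture retains on average about
#'   114 detectable clones by day 45.
#' @param sort_days,sort_loss Optional sort event days and the per-clone loss
#'   probability applied at each.
#' @return A data frame with columns `day`, `event`, `size`, `fraction`,
#'   sorted by day, of class `culture_schedule`.
#' @export
culture_schedule <- function(passage_days = seq(4, 46, by = 3),
                             bottleneck = 1900,
                             sort_days = numeric(0), sort_loss = 0.3) {
  sched <- rbind(
    if (length(passage_days))
      data.frame(day = passage_days, event = "passage",
                 size = bottleneck, fraction = NA_real_),
    if (length(sort_days))
      data.frame(day = sort_days, event = "sort",
                 size = NA_real_, fraction = sort_loss)
  )
  if (is.null(sched))
    sched <- data.frame(day = numeric(0), event = character(0),
                        size = numeric(0), fraction = numeric(0))
  sched <- sched[order(sched$day), , drop = FALSE]
  rownames(sched) <- NULL
  validate_culture_schedule(sched)
  class(sched) <- c("culture_schedule", "data.frame")
  sched
}

validate_culture_schedule <- function(sched) {
  if (!all(c("day", "event", "size", "fraction") %in% names(sched)))
    stop("schedule must have columns day, event, size, fraction", call. = FALSE)
  if (nrow(sched) == 0) return(invisible(sched))
  if (is.unsorted(sched$day, strictly = TRUE))
    stop("schedule days must be strictly increasing", call. = FALSE)
  if (!all(sched$event %in% c("passage", "sort")))
    stop("schedule events must be \"passage\" or \"sort\"", call. = FALSE)
  pas <- sched$event == "passage"
  if (any(is.na(sched$size[pas])) || any(sched$size[pas] <= 0))
    stop("passage events need a positive bottleneck size", call. = FALSE)
  srt <- sched$event == "sort"
  if (any(is.na(sched$fraction[srt])) || any(sched$fraction[srt] < 0) ||
      any(sched$fraction[srt] > 1))
    stop("sort events need a loss fraction in [0, 1]", call. = FALSE)
  invisible(sched)
}

#' Simulate clonal drift during in vitro culture
#'
#' Discrete-generation stochastic birth-death with multinomial passaging
#' bottlenecks. Between events every clone grows by an expected factor
#' `2^(days / doubling_days * (1 + fitness))` with Poisson offspring noise; at
#' each `passage` the culture is multinomially resampled down to the
#' bottleneck; at each `sort` clones are removed independently with the given
#' probability. Clone richness is non-increasing (no clones are ever added).
#'
#' @param pop Starting [clone_population()] (its `day` attribute anchors the
#'   schedule).
#' @param schedule A [culture_schedule()]; an empty schedule returns the input
#'   unchanged (as a one-element trajectory).
#' @param seed Integer seed.
#' @param initial_cells Cell count at the starting day (abundances are
#'   converted to integer counts of this total).
#' @param doubling_days Population doubling time in days (default 1, typical
#'   of cytokine-independent Ba/F3 growth).
#' @return A list of `clone_population` snapshots (the trajectory), one for
#'   the start day and one per scheduled event. Clones that die out are kept
#'   with abundance 0 in snapshots so trajectories are column-stable.
#' @export
simulate_culture <- function(pop, schedule = culture_schedule(), seed = 1L,
                             initial_cells = 1900, doubling_days = 1) {
  stopifnot(inherits(pop, "clone_population"))
  validate_culture_schedule(schedule)
  if (doubling_days <= 0 || initial_cells <= 0)
    stop("growth parameters must be positive", call. = FALSE)
  if (any(pop$abundance < 0))
    stop("abundances must be non-negative", call. = FALSE)
  day0 <- attr(pop, "day")
  if (nrow(schedule) && schedule$day[1] <= day0)
    stop("schedule must start after the population's day", call. = FALSE)

  snap <- function(counts, day) {
    p <- pop
    p$abundance <- if (sum(counts) > 0) counts / sum(counts) else counts
    attr(p, "day") <- day
    p
  }
  traj <- list(snap(pop$abundance, day0))
  if (nrow(schedule) == 0) return(traj)

  set.seed(seed)
  counts <- as.numeric(stats::rmultinom(1, initial_cells, pop$abundance))
  day <- day0
  for (i in seq_len(nrow(schedule))) {
    dt <- schedule$day[i] - day
    growth <- 2^(dt / doubling_days * (1 + pop$fitness))
    counts <- stats::rpois(length(counts), counts * growth)
    if (schedule$event[i] == "passage") {
      if (sum(counts) > 0) {
        size <- min(schedule$size[i], sum(counts))
        counts <- as.numeric(stats::rmultinom(1, size, counts))
      }
    } else { # sort
      lost <- stats::runif(length(counts)) < schedule$fraction[i]
      counts[lost] <- 0
    }
    day <- schedule$day[i]
    traj[[length(traj) + 1L]] <- snap(counts, day)
  }
  traj
}
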