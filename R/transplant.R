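#' Specify a transplant graft
#'
#' Clone frequencies of a sequenced graft plus the number of cells
#' transplanted. Clones not listed are pooled into a single aggregate `bulk`
#' clone holding the remaining fraction (the identity of the many minor bulk
#' clones does not influence outcome classification).
#'
#' @param clones Data frame with columns `clone_id`, `class`
#'   (`"A"`, `"B"` or `"bulk"`) and `fraction` (in `[0, 1]`, summing to at
#'   most 1).
#' @param n_cells Number of transplanted cells (e.g. 1000 or 10000).
#' @param label Cohort label.
#' @return An object of class `graft_spec`.
#' @export
graft_spec <- function(clones, n_cells, label = "graft") {
  stopifnot(is.data.frame(clones),
            all(c("clone_id", "class", "fraction") %in% names(clones)))
  if (any(clones$fraction < 0) || any(clones$fraction > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (sum(clones$fraction) > 1 + 1e-12)
    stop("clone fractions sum to more than 1", call. = FALSE)
  if (!all(clones$class %in% c("bulk", "A", "B")))
    stop("graft classes must be bulk/A/B", call. = FALSE)
  if (anyDuplicated(clones$clone_id))
    stop("duplicate clone ids in graft spec", call. = FALSE)
  if (n_cells < 0) stop("`n_cells` must be >= 0", call. = FALSE)
  rest <- 1 - sum(clones$fraction)
  if (rest > 1e-12 && !"bulk" %in% clones$clone_id) {
    clones <- rbind(clones[, c("clone_id", "class", "fraction")],
                    data.frame(clone_id = "bulk", class = "bulk",
                               fraction = rest))
  }
  structure(list(clones = clones, n_cells = n_cells, label = label),
            class = "graft_spec")
}

#' Day-29 and day-49 graft compositions
#'
#' Convenience constructors for the two observed graft compositions: at day
#' 29 of culture clone A held 0.47% and clone B 0.65% of reads; at day 49,
#' 20.4% and 10.1%.
#'
#' @param n_cells Transplanted cell number.
#' @return A [graft_spec()].
#' @export
graft_d29 <- function(n_cells = 10000) {
  graft_spec(data.frame(clone_id = c("A", "B"), class = c("A", "B"),
                        fraction = c(0.0047, 0.0065)),
             n_cells = n_cells, label = sprintf("d29_%d", n_cells))
}

#' @rdname graft_d29
#' @export
graft_d49 <- function(n_cells = 10000) {
  graft_spec(data.frame(clone_id = c("A", "B"), class = c("A", "B"),
                        fraction = c(0.204, 0.101)),
             n_cells = n_cells, label = sprintf("d49_%d", n_cells))
}

#' Sample a graft inoculum
#'
#' Multinomial draw of `n_cells` over the graft's clone frequencies.
#'
#' @param spec A [graft_spec()].
#' @param seed Integer seed, or `NULL` to continue the RNG stream.
#' @return Named integer vector of per-clone cell counts (attribute `class`
#'   maps clones to classes).
#' @export
sample_graft <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "graft_spec"))
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(spec$clones)
  counts <- if (spec$n_cells == 0 || k == 0) {
    integer(k)
  } else {
    as.integer(stats::rmultinom(1, spec$n_cells, spec$clones$fraction))
  }
  names(counts) <- spec$clones$clone_id
  attr(counts, "class_of") <- stats::setNames(spec$clones$class,
                                              spec$clones$clone_id)
  counts
}

#' Engraftment model: class-specific initial-affinity distributions
#'
#' Each transplanted cell draws its initial attachment affinity from a
#' Beta distribution scaled to `[0, a_max]` whose mean depends on its class;
#' cells then attempt niche attachment for `window_hours` before being lost.
#' A single shared `ab_shift` moves the A and B means up from the bulk mean
#' (the two driver clones are treated as structurally similar), keeping
#' calibration identifiable. Means of exactly 0 yield a point mass at zero
#' affinity (no attachment possible).
#'
#' @param mean_bulk Mean initial affinity of bulk (and host) cells, as a
#'   fraction of `a_max`. The calibrated default is effectively zero: a low
#'   overall engraftment is required to reproduce the observed cell-number
#'   dependence.
#' @param ab_shift Additive shift of the A/B mean over `mean_bulk`.
#' @param concentration Beta concentration parameter (shape1 + shape2).
#' @param window_hours Engraftment window (default 48 h).
#' @return An object of class `engraftment_model`.
#' @export
engraftment_model <- function(mean_bulk = 1e-6, ab_shift = 0.02,
                              concentration = 1, window_hours = 48) {
  if (mean_bulk < 0 || mean_bulk >= 1 || ab_shift < 0 ||
      mean_bulk + ab_shift >= 1)
    stop("class means must lie in [0, 1)", call. = FALSE)
  if (concentration <= 0 || window_hours <= 0)
    stop("concentration and window must be positive", call. = FALSE)
  structure(list(mean = c(host = mean_bulk, bulk = mean_bulk,
                          A = mean_bulk + ab_shift, B = mean_bulk + ab_shift),
                 concentration = concentration,
                 window_hours = window_hours),
            class = "engraftment_model")
}

# initial affinities for n cells of one class, in [0, a_max]
.draw_affinity <- function(n, class, engraftment, a_max) {
  mu <- engraftment$mean[[class]]
  if (n == 0) return(numeric(0))
  if (mu <= 0) return(rep(0, n)) # degenerate: consumes no RNG
  k <- engraftment$concentration
  a_max * stats::rbeta(n, k * mu, k * (1 - mu))
}

#' Transplant a graft onto a steady-state host
#'
#' Adds the grafted cells in the pre-engraftment state to an unconditioned
#' host (niches at their homeostatic occupancy; no conditioning-induced
#' clearance), lets them attempt attachment during the engraftment window,
#' and advances the model day by day up to `horizon_days`. The run stops
#' early once the leukemia criterion is met: leukemic cells (live plus
#' cumulative differentiated output of classes bulk/A/B) reaching at least
#' `criterion$threshold` of the total stem pool plus output.
#'
#' The seed is split into a graft-preparation stream (initial affinities)
#' and a simulation stream, both reported in the result, so an
#' untransplanted control can be run on an identical simulation stream.
#'
#' @param host A converged [run_to_steady_state()] state.
#' @param graft Named per-clone cell counts from [sample_graft()] (scaled by
#'   `params$pool_scale` before use, rounding stochastically).
#' @param engraftment An [engraftment_model()].
#' @param params A [model_params()].
#' @param horizon_days Observation horizon (default 25).
#' @param criterion List with `threshold` (leukemic fraction declaring
#'   disease, default 0.2).
#' @param seed Integer seed.
#' @param t_mono,t_minor Dominance thresholds passed to
#'   [classify_dominance()].
#' @param analysis_delay_days Days the model keeps running after the
#'   criterion is met before the clonal composition is read (default 4),
#'   mirroring the delay between disease detection and sacrifice: by
#'   analysis the outgrowing clone has expanded well past transient dying
#'   lineages.
#' @return An object of class `transplant_outcome`: list with `leukemic`,
#'   `latency_days` (first day the criterion held, else `NA`), `dominance`
#'   (a [classify_dominance()] call over leukemic clone totals; category
#'   `no_leukemia` when not leukemic), `engrafted_counts` (per clone),
#'   `leukemic_fraction` at stop, `n_lost` and `seeds`.
#' @export
transplant <- function(host, graft, engraftment, params = model_params(),
                       horizon_days = 25, criterion = list(threshold = 0.2),
                       seed = 1L, t_mono = 0.90, t_minor = 0.10,
                       analysis_delay_days = 4) {
  stopifnot(inherits(host, "model_state"),
            inherits(engraftment, "engraftment_model"))
  validate_model_params(params)
  if (!isTRUE(host$converged))
    stop("host state has not converged to steady state", call. = FALSE)
  if (horizon_days <= 0) stop("`horizon_days` must be positive", call. = FALSE)
  set.seed(seed)
  seed_graft <- sample.int(.Machine$integer.max - 1L, 1)
  seed_sim <- sample.int(.Machine$integer.max - 1L, 1)

  class_of <- attr(graft, "class_of")
  set.seed(seed_graft)
  graft_n <- vapply(as.numeric(graft), function(g) {
    g <- g * params$pool_scale
    as.numeric(floor(g) + (stats::runif(1) < g - floor(g)))
  }, numeric(1))
  aff <- unlist(lapply(seq_along(graft), function(i) {
    .draw_affinity(graft_n[i], class_of[[names(graft)[i]]], engraftment,
                   params$a_max)
  }), use.names = FALSE)
  n_new <- sum(graft_n)
  new_cells <- data.frame(
    clone_id = rep(names(graft), graft_n),
    class = rep(unname(class_of[names(graft)]), graft_n),
    compartment = rep("pre", n_new),
    affinity = if (n_new) aff else numeric(0),
    cycle = rep(0, n_new),
    window = rep(engraftment$window_hours, n_new),
    stringsAsFactors = FALSE
  )
  # output is accounted from transplantation time onward
  diff0 <- host$diff_out
  diff0[] <- 0
  state <- model_state(rbind(host$cells, new_cells), t = host$t,
                       diff_out = diff0, n_lost = 0L)
  state$converged <- TRUE

  leukemic_stats <- function(s) {
    live <- s$cells[s$cells$compartment != "pre", ]
    leu_live <- live[live$class != "host", ]
    cls_of <- .clone_classes(s)
    leu_clones <- names(cls_of)[cls_of != "host"]
    leu_tot <- stats::setNames(numeric(length(leu_clones)), leu_clones)
    leu_alive <- leu_tot
    if (length(leu_clones)) {
      tab <- table(factor(leu_live$clone_id, leu_clones))
      leu_alive <- stats::setNames(as.numeric(tab), leu_clones)
      leu_tot <- leu_alive + s$diff_out[leu_clones]
    }
    total <- nrow(live) + sum(s$diff_out)
    # the disease criterion counts live cells plus cumulative output; the
    # clonal composition is read from cells alive at analysis, as a barcode
    # readout of hematopoietic organs would see it
    list(per_clone = leu_tot, per_clone_live = leu_alive,
         fraction = if (total > 0) sum(leu_tot) / total else 0)
  }

  set.seed(seed_sim)
  state <- run_model(state, params,
                     steps = round(horizon_days * 24 / params$dt),
                     check_every = round(24 / params$dt),
                     leukemia_threshold = criterion$threshold)
  eng <- attr(state, "engrafted")
  engrafted <- stats::setNames(numeric(length(graft)), names(graft))
  common <- intersect(names(eng), names(engrafted))
  engrafted[common] <- engrafted[common] + eng[common]
  stats <- leukemic_stats(state)
  leukemic <- isTRUE(attr(state, "crossed"))
  latency <- if (leukemic)
    ceiling(attr(state, "steps_run") * params$dt / 24) else NA_real_
  if (leukemic && analysis_delay_days > 0) {
    # detection-to-sacrifice delay: composition is read at analysis
    state <- run_model(state, params,
                       steps = round(analysis_delay_days * 24 / params$dt))
    stats <- leukemic_stats(state)
  }
  dominance <- if (leukemic && sum(stats$per_clone_live) > 0) {
    classify_dominance(stats$per_clone_live[stats$per_clone_live > 0],
                       t_mono = t_mono, t_minor = t_minor,
                       leukemia_flag = TRUE)
  } else {
    classify_dominance(c(none = 1), leukemia_flag = FALSE)
  }
  structure(list(leukemic = leukemic, latency_days = latency,
                 dominance = dominance,
                 engrafted_counts = engrafted,
                 leukemic_fraction = stats$fraction,
                 n_lost = state$n_lost,
                 final_state = state,
                 seeds = list(graft = seed_graft, sim = seed_sim)),
            class = "transplant_outcome")
}

#' @export
print.transplant_outcome <- function(x, ...) {
  if (x$leukemic) {
    cat(sprintf("Transplant outcome: leukemia at day %g (%s), leukemic fraction %.2f\n",
                x$latency_days, x$dominance$category, x$leukemic_fraction))
  } else {
    cat("Transplant outcome: no leukemia within horizon\n")
  }
  cat(sprintf("  engrafted cells: %s\n",
              paste(sprintf("%s=%g", names(x$engrafted_counts),
                            x$engrafted_counts), collapse = ", ")))
  invisible(x)
}

#' Simulate a transplantation cohort
#'
#' Runs `R` independent in silico transplantations (a fresh multinomial graft
#' sample per recipient) of one graft specification onto a shared
#' steady-state host, and aggregates the outcome spectrum.
#'
#' @param spec A [graft_spec()].
#' @param engraftment An [engraftment_model()].
#' @param params A [model_params()].
#' @param R Number of replicate recipients (default 250).
#' @param seed Integer seed.
#' @param horizon_days,criterion,t_mono,t_minor See [transplant()].
#' @param host Optional pre-computed steady-state host used for every
#'   replicate. By default (`NULL`) a fresh steady-state host is simulated
#'   for every `replicates_per_host` recipients, so recipient-to-recipient
#'   variability of the host niche is part of the cohort statistics.
#' @param replicates_per_host Recipients sharing one simulated host when
#'   `host = NULL` (default 10).
#' @return An object of class `cohort_summary`: per-outcome fractions
#'   (`fraction_no`, `fraction_mono`, `fraction_bi`, `fraction_poly`,
#'   summing to 1), the leukemia `incidence`, the dominant-clone identity
#'   spectrum, and the per-replicate outcome table.
#' @export
run_cohort <- function(spec, engraftment, params = model_params(), R = 250,
                       seed = 1L, horizon_days = 25,
                       criterion = list(threshold = 0.2), t_mono = 0.90,
                       t_minor = 0.10, host = NULL,
                       replicates_per_host = 10L) {
  stopifnot(inherits(spec, "graft_spec"))
  if (R < 1) stop("`R` must be >= 1", call. = FALSE)
  set.seed(seed)
  host_seeds <- sample.int(.Machine$integer.max - 1L,
                           ceiling(R / replicates_per_host))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, 2 * R)
  fixed_host <- !is.null(host)
  if (fixed_host && !isTRUE(host$converged))
    stop("host did not reach steady state; adjust parameters", call. = FALSE)
  rows <- vector("list", R)
  for (i in seq_len(R)) {
    if (!fixed_host && (i - 1L) %% replicates_per_host == 0L) {
      host <- run_to_steady_state(params,
                                  seed = host_seeds[(i - 1L) %/%
                                                      replicates_per_host + 1L])
      if (!isTRUE(host$converged))
        stop("host did not reach steady state; adjust parameters",
             call. = FALSE)
    }
    g <- sample_graft(spec, seed = rep_seeds[2 * i - 1])
    out <- transplant(host, g, engraftment, params,
                      horizon_days = horizon_days, criterion = criterion,
                      seed = rep_seeds[2 * i], t_mono = t_mono,
                      t_minor = t_minor)
    rows[[i]] <- data.frame(
      replicate = i,
      category = out$dominance$category,
      latency_days = out$latency_days,
      dominant = paste(sort(out$dominance$dominant_clones$clone),
                       collapse = "+"),
      n_engrafted = sum(out$engrafted_counts),
      leukemic_fraction = out$leukemic_fraction,
      stringsAsFactors = FALSE)
  }
  outcomes <- do.call(rbind, rows)
  frac <- function(cat) mean(outcomes$category == cat)
  structure(list(
    label = spec$label, n_replicates = R,
    fraction_no = frac("no_leukemia"),
    fraction_mono = frac("monoclonal"),
    fraction_bi = frac("biclonal"),
    fraction_poly = frac("polyclonal"),
    incidence = mean(outcomes$category != "no_leukemia"),
    dominant_spectrum = table(outcomes$dominant[outcomes$dominant != ""]),
    outcomes = outcomes,
    settings = list(horizon_days = horizon_days, criterion = criterion,
                    t_mono = t_mono, t_minor = t_minor, seed = seed)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort '%s': %d replicates\n", x$label, x$n_replicates))
  cat(sprintf("  no leukemia: %.1f%%  monoclonal: %.1f%%  biclonal: %.1f%%  polyclonal: %.1f%%\n",
              100 * x$fraction_no, 100 * x$fraction_mono,
              100 * x$fraction_bi, 100 * x$fraction_poly))
  cat(sprintf("  leukemia incidence: %.1f%%\n", 100 * x$incidence))
  if (length(x$dominant_spectrum)) {
    cat("  dominant clones: ",
        paste(sprintf("%s (%d)", names(x$dominant_spectrum),
                      as.integer(x$dominant_spectrum)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a cohort summary
#'
#' `write_cohort_tsv` writes the cohort-level outcome fractions as a one-row
#' TSV (`cohort`, `fraction_no`, `fraction_mono`, `fraction_bi`,
#' `fraction_poly`, `incidence`); `write_cohort_json` writes the full summary
#' including per-replicate outcomes.
#'
#' @param x A `cohort_summary` (or list of them for the TSV writer).
#' @param path Output path.
#' @export
write_cohort_tsv <- function(x, path) {
  if (inherits(x, "cohort_summary")) x <- list(x)
  df <- do.call(rbind, lapply(x, function(s)
    data.frame(cohort = s$label, n_replicates = s$n_replicates,
               fraction_no = s$fraction_no, fraction_mono = s$fraction_mono,
               fraction_bi = s$fraction_bi, fraction_poly = s$fraction_poly,
               incidence = s$incidence, stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
write_cohort_json <- function(x, path) {
  stopifnot(inherits(x, "cohort_summary"))
  jsonlite::write_json(
    list(label = x$label, n_replicates = x$n_replicates,
         fraction_no = x$fraction_no, fraction_mono = x$fraction_mono,
         fraction_bi = x$fraction_bi, fraction_poly = x$fraction_poly,
         incidence = x$incidence,
         dominant_spectrum = as.list(x$dominant_spectrum),
         outcomes = x$outcomes),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate one full two-dose transplantation experiment
#'
#' Emulates the first in vivo experiment: `n_per_dose` recipients at 1,000
#' cells and `n_per_dose` at 10,000 cells from the same graft frequencies,
#' classifying every recipient.
#'
#' @param engraftment,params,criterion,t_mono,t_minor See [run_cohort()].
#' @param n_per_dose Recipients per dose arm (default 15).
#' @param doses Transplanted cell numbers (default `c(1000, 10000)`).
#' @param spec_fun Function `n_cells -> graft_spec` (default [graft_d29()]).
#' @param horizon_days Observation horizon (default 25).
#' @param seed Integer seed.
#' @param host Optional shared steady-state host; by default each arm
#'   rotates fresh hosts (see [run_cohort()]).
#' @return Data frame of per-recipient outcomes with columns `dose`,
#'   `category`, `dominant`; attribute `n_monoclonal` gives the monoclonal
#'   leukemia count across both arms.
#' @export
simulate_experiment <- function(engraftment, params = model_params(),
                                n_per_dose = 15, doses = c(1000, 10000),
                                spec_fun = graft_d29, horizon_days = 25,
                                criterion = list(threshold = 0.2),
                                t_mono = 0.90, t_minor = 0.10, seed = 1L,
                                host = NULL) {
  set.seed(seed)
  arm_seeds <- sample.int(.Machine$integer.max - 1L, length(doses))
  arms <- lapply(seq_along(doses), function(i) {
    cs <- run_cohort(spec_fun(doses[i]), engraftment, params, R = n_per_dose,
                     seed = arm_seeds[i], horizon_days = horizon_days,
                     criterion = criterion, t_mono = t_mono,
                     t_minor = t_minor, host = host)
    data.frame(dose = doses[i], category = cs$outcomes$category,
               dominant = cs$outcomes$dominant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, arms)
  attr(out, "n_monoclonal") <- sum(out$category == "monoclonal")
  out
}
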