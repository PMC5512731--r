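CLASS_LEVELS <- c("host", "bulk", "A", "B")

#' Parameters of the niche-competition stem-cell model
#'
#' The model tracks individual cells in two compartments: `A`, the
#' niche-attached quiescent state, and `Omega`, the actively cycling state.
#' Each cell has an attachment affinity `a` in `[a_min, a_max]` that is
#' multiplied by `r` per time step while in `A` and divided by `d` per step
#' while in `Omega`; cells whose affinity drops below `a_min` leave the stem
#' pool as differentiated output. Per-step transition probabilities are
#' `alpha(a, N_A) = (a / a_max) * f_alpha(N_A / N_bar_A)` for (re)attachment
#' and `omega(a, N_Omega) = (a_min / a) * f_omega(N_Omega / N_bar_Omega)` for
#' release, each multiplied by a per-class modifier and clipped to `[0, 1]`.
#' `f_alpha` and `f_omega` are 4-coefficient sigmoids
#' `f(x) = f_min + (f_max - f_min) / (1 + exp(slope * (x - x_half)))`, so
#' both decrease as the corresponding compartment fills. Cells in `Omega`
#' divide every `tau_c` hours (affinity inherited by both daughters).
#'
#' Leukemic classes (`bulk`, `A`, `B`) differ from host cells only through
#' the multiplicative `alpha_mult` / `omega_mult` modifiers: a raised
#' `omega_mult` encodes the increased activation/proliferation drive of the
#' oncogene-transformed cells, and a raised `alpha_mult` their increased
#' propensity to (re)occupy niche space.
#'
#' @param a_min,a_max Affinity bounds (defaults 0.002 and 1).
#' @param r Per-step affinity regeneration factor in `A` (> 1).
#' @param d Per-step affinity attenuation factor in `Omega` (> 1).
#' @param tau_c Cell-cycle duration in hours (default 24).
#' @param dt Time step in hours (default 1).
#' @param f_alpha,f_omega Sigmoid coefficients `c(f_max, x_half, slope,
#'   f_min)` for attachment and release.
#' @param N_bar_A,N_bar_Omega Scaling pool sizes for the two compartments at
#'   `pool_scale = 1` (default 2000 niche slots, a desk-scale population).
#' @param alpha_mult,omega_mult Named per-class multiplicative modifiers
#'   (`host`, `bulk`, `A`, `B`).
#' @param death_rate Optional per-class per-step death probability
#'   (default 0; death is excluded from the baseline model).
#' @param pool_scale Global scaling of pool sizes (and, in
#'   [run_cohort()]/[transplant()], of transplanted cell numbers); reported
#'   fractions are scale-free.
#' @return An object of class `model_params`.
#' @export
model_params <- function(a_min = 0.002, a_max = 1, r = 2.2, d = 1.02,
                         tau_c = 24, dt = 1,
                         f_alpha = c(f_max = 0.05, x_half = 0.5, slope = 18,
                                     f_min = 5e-4),
                         f_omega = c(f_max = 0.02, x_half = 0.5, slope = 6,
                                     f_min = 0.002),
                         N_bar_A = 2000, N_bar_Omega = 2000,
                         alpha_mult = c(host = 1, bulk = 3, A = 3, B = 3),
                         omega_mult = c(host = 1, bulk = 1500, A = 1500, B = 1500),
                         death_rate = c(host = 0, bulk = 0, A = 0, B = 0),
                         pool_scale = 1) {
  p <- structure(list(
    a_min = a_min, a_max = a_max, r = r, d = d, tau_c = tau_c, dt = dt,
    f_alpha = unname(f_alpha), f_omega = unname(f_omega),
    N_bar_A = N_bar_A, N_bar_Omega = N_bar_Omega,
    alpha_mult = .class_vec(alpha_mult), omega_mult = .class_vec(omega_mult),
    death_rate = .class_vec(death_rate), pool_scale = pool_scale
  ), class = "model_params")
  validate_model_params(p)
}

.class_vec <- function(x) {
  if (is.null(names(x))) {
    x <- rep_len(x, length(CLASS_LEVELS))
    names(x) <- CLASS_LEVELS
  } else {
    miss <- setdiff(CLASS_LEVELS, names(x))
    if (length(miss))
      stop("per-class parameter missing classes: ",
           paste(miss, collapse = ", "), call. = FALSE)
    x <- x[CLASS_LEVELS]
  }
  x
}

#' @rdname model_params
#' @param p A `model_params` object.
#' @export
validate_model_params <- function(p) {
  stopifnot(inherits(p, "model_params"))
  if (!(p$a_min > 0 && p$a_min < p$a_max))
    stop("need 0 < a_min < a_max", call. = FALSE)
  if (p$r <= 1 || p$d <= 1)
    stop("affinity factors r and d must exceed 1", call. = FALSE)
  if (p$dt <= 0 || p$tau_c <= 0)
    stop("tau_c and dt must be positive", call. = FALSE)
  for (f in list(p$f_alpha, p$f_omega)) {
    if (length(f) != 4)
      stop("sigmoid coefficient vectors need 4 entries", call. = FALSE)
    if (f[1] < 0 || f[1] > 1 || f[4] < 0 || f[4] > 1)
      stop("sigmoid asymptotes must lie in [0, 1]", call. = FALSE)
  }
  if (p$N_bar_A <= 0 || p$N_bar_Omega <= 0 || p$pool_scale <= 0)
    stop("pool sizes and pool_scale must be positive", call. = FALSE)
  if (any(p$alpha_mult < 0) || any(p$omega_mult < 0))
    stop("class modifiers must be non-negative", call. = FALSE)
  if (any(p$death_rate < 0) || any(p$death_rate > 1))
    stop("death rates must be probabilities", call. = FALSE)
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Niche-competition model parameters\n")
  cat(sprintf("  affinity: [%g, %g], r = %g, d = %g; tau_c = %g h, dt = %g h\n",
              x$a_min, x$a_max, x$r, x$d, x$tau_c, x$dt))
  cat(sprintf("  pools: N_bar_A = %g, N_bar_Omega = %g (pool_scale = %g)\n",
              x$N_bar_A, x$N_bar_Omega, x$pool_scale))
  cat(sprintf("  leukemic modifiers: alpha x%g, omega x%g\n",
              x$alpha_mult[["A"]], x$omega_mult[["A"]]))
  invisible(x)
}

# Parameter list as consumed by the compiled core (pool_scale applied).
.par_for_cpp <- function(p) {
  list(a_min = p$a_min, a_max = p$a_max, r = p$r, d = p$d, tau_c = p$tau_c,
       dt = p$dt, f_alpha = as.numeric(p$f_alpha),
       f_omega = as.numeric(p$f_omega),
       N_bar_A = p$N_bar_A * p$pool_scale,
       N_bar_Omega = p$N_bar_Omega * p$pool_scale,
       alpha_mult = as.numeric(p$alpha_mult),
       omega_mult = as.numeric(p$omega_mult),
       death_rate = as.numeric(p$death_rate))
}

#' Per-step transition probabilities
#'
#' Evaluates the attachment probability `alpha` and release probability
#' `omega` for given affinities, compartment censuses and cell classes (see
#' [model_params()] for the functional forms). Vectorized over `a`.
#'
#' @param a Affinity value(s) in `[a_min, a_max]`.
#' @param N_A,N_Omega Compartment censuses (recycled).
#' @param params A [model_params()].
#' @param class Cell class (`"host"`, `"bulk"`, `"A"`, `"B"`), recycled.
#' @return Matrix with columns `alpha` and `omega`, one row per input, all
#'   values in `[0, 1]`.
#' @export
transition_probabilities <- function(a, N_A, N_Omega, params = model_params(),
                                     class = "host") {
  validate_model_params(params)
  cls <- match(class, CLASS_LEVELS) - 1L
  if (anyNA(cls)) stop("unknown cell class", call. = FALSE)
  .ck_transition_probabilities(as.numeric(a), as.numeric(N_A),
                               as.numeric(N_Omega), as.integer(cls),
                               .par_for_cpp(params))
}
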