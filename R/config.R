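#' Read and write model configurations as YAML
#'
#' A configuration bundles everything a transplantation study needs: the
#' [model_params()], the [engraftment_model()], the leukemia criterion and
#' the observation horizon. The package ships two configurations under
#' `inst/extdata/`: `model-default.yaml` (host homeostasis parameters with
#' neutral leukemic modifiers) and `model-calibrated.yaml` (the calibrated
#' study configuration used for the in silico transplantation cohorts).
#'
#' @param path YAML file path.
#' @return `read_model_config` returns a list with elements `params`
#'   (`model_params`), `engraftment` (`engraftment_model`), `criterion` and
#'   `horizon_days`.
#' @export
read_model_config <- function(path) {
  y <- yaml::read_yaml(path)
  mp <- y$model
  params <- model_params(
    a_min = mp$a_min, a_max = mp$a_max, r = mp$r, d = mp$d,
    tau_c = mp$tau_c, dt = mp$dt,
    f_alpha = unlist(mp$f_alpha), f_omega = unlist(mp$f_omega),
    N_bar_A = mp$N_bar_A, N_bar_Omega = mp$N_bar_Omega,
    alpha_mult = unlist(mp$alpha_mult), omega_mult = unlist(mp$omega_mult),
    death_rate = unlist(mp$death_rate), pool_scale = mp$pool_scale
  )
  em <- y$engraftment
  engraftment <- engraftment_model(
    mean_bulk = em$mean_bulk, ab_shift = em$ab_shift,
    concentration = em$concentration, window_hours = em$window_hours
  )
  list(params = params, engraftment = engraftment,
       criterion = list(threshold = y$criterion$threshold),
       horizon_days = y$horizon_days)
}

#' @rdname read_model_config
#' @param config List as returned by `read_model_config`.
#' @export
write_model_config <- function(config, path) {
  p <- config$params
  em <- config$engraftment
  yaml::write_yaml(list(
    model = list(
      a_min = p$a_min, a_max = p$a_max, r = p$r, d = p$d, tau_c = p$tau_c,
      dt = p$dt, f_alpha = as.numeric(p$f_alpha),
      f_omega = as.numeric(p$f_omega), N_bar_A = p$N_bar_A,
      N_bar_Omega = p$N_bar_Omega, alpha_mult = as.list(p$alpha_mult),
      omega_mult = as.list(p$omega_mult), death_rate = as.list(p$death_rate),
      pool_scale = p$pool_scale
    ),
    engraftment = list(
      mean_bulk = em$mean[["bulk"]],
      ab_shift = em$mean[["A"]] - em$mean[["bulk"]],
      concentration = em$concentration, window_hours = em$window_hours
    ),
    criterion = list(threshold = config$criterion$threshold),
    horizon_days = config$horizon_days
  ), path)
  invisible(path)
}

#' Load a configuration shipped with the package
#'
#' @param name `"calibrated"` (default) or `"default"`.
#' @return See [read_model_config()].
#' @export
shipped_config <- function(name = c("calibrated", "default")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("model-", name, ".yaml"),
                      package = "clonekinetics")
  if (path == "") stop("shipped config not found", call. = FALSE)
  read_model_config(path)
}
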