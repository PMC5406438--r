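#' Section temperature from run current
#'
#' Estimates the local electrolyte temperature in one capillary section from
#' the plateau current. The temperature rise above the coolant setpoint is
#' modelled as proportional to the dissipated electrical power per unit
#' length, `U * I / L_tot`, with a section-specific heat-transfer coefficient
#' (see [sumet_parameters()]): the non-thermostated inlet heats more than the
#' actively cooled core.
#'
#' @param T_coolant_C nominal coolant temperature (degC).
#' @param U_nom_kV separation voltage (kV).
#' @param current_uA plateau current (uA); must be present (no silent skip).
#' @param geometry a [capillary_geometry].
#' @param params a [sumet_parameters].
#' @param section `"cooled"` (thermostated core) or `"noncooled"` (inlet).
#' @return Local section temperature (degC), vectorized.
#' @examples
#' g <- capillary_geometry()
#' p <- sumet_parameters(kappa_noncooled = 2, kappa_cooled = 0.4)
#' sumet_section_temperature(25, 30, 50, g, p, "noncooled")  # 30 degC
#' @export
sumet_section_temperature <- function(T_coolant_C, U_nom_kV, current_uA,
                                      geometry, params,
                                      section = c("cooled", "noncooled")) {
  section <- match.arg(section)
  stopifnot(inherits(geometry, "capillary_geometry"),
            inherits(params, "sumet_parameters"))
  if (any(is.na(current_uA)))
    stop("run current is required for thermal correction but is missing")
  if (any(current_uA < 0))
    stop("current must be non-negative")
  power_per_length <- abs(U_nom_kV * KV_TO_V) * current_uA * 1e-6 / geometry$L_tot
  kappa <- switch(section, cooled = params$kappa_cooled,
                  noncooled = params$kappa_noncooled)
  T_coolant_C + kappa * power_per_length
}

#' Length-weighted actual electrolyte temperature
#'
#' Combines the inlet-section and core-section temperatures into the
#' effective temperature the computed mobility refers to, weighting each
#' section by the fraction of the migration path it occupies:
#' `T_actual = T_inlet * L_inlet/L_eff + T_core * (L_eff - L_inlet)/L_eff`.
#' The section beyond the detector never affects migration to the detector
#' and is ignored. Alternative inlet weights can be supplied through
#' `w_inlet` (the core weight is its complement).
#'
#' @param T_inlet,T_core section temperatures (degC), vectorized.
#' @param geometry a [capillary_geometry].
#' @param w_inlet optional inlet weight overriding the length-derived
#'   default `L_inlet / L_eff`; must lie in `[0, 1]`.
#' @return A data.frame of class `"temperature_estimate"` with columns
#'   `T_inlet`, `T_core`, `T_actual`.
#' @export
actual_temperature <- function(T_inlet, T_core, geometry, w_inlet = NULL) {
  stopifnot(inherits(geometry, "capillary_geometry"))
  if (is.null(w_inlet)) w_inlet <- geometry$L_inlet / geometry$L_eff
  if (w_inlet < 0 || w_inlet > 1) stop("w_inlet must lie in [0, 1]")
  out <- data.frame(T_inlet = T_inlet, T_core = T_core,
                    T_actual = w_inlet * T_inlet + (1 - w_inlet) * T_core)
  class(out) <- c("temperature_estimate", "data.frame")
  out
}

#' Per-run actual temperatures for a run table
#'
#' Convenience wrapper applying [sumet_section_temperature()] to both
#' sections and [actual_temperature()] to every run.
#'
#' @param runs a validated run table.
#' @inheritParams actual_temperature
#' @param params a [sumet_parameters].
#' @return `runs` with `T_inlet`, `T_core`, `T_actual` columns appended.
#' @export
run_temperature <- function(runs, geometry, params, w_inlet = NULL) {
  runs <- validate_run_table(runs)
  T_in <- sumet_section_temperature(runs$T_coolant_C, runs$U_nom_kV,
                                    runs$current_uA, geometry, params,
                                    "noncooled")
  T_co <- sumet_section_temperature(runs$T_coolant_C, runs$U_nom_kV,
                                    runs$current_uA, geometry, params,
                                    "cooled")
  est <- actual_temperature(T_in, T_co, geometry, w_inlet)
  cbind(runs, as.data.frame(est))
}

#' Mobility-versus-temperature model
#'
#' Fits a polynomial (default degree 2) describing the electrophoretic
#' mobility of one species in one buffer as a function of the actual
#' electrolyte temperature. The model is then read out at temperatures of
#' interest ([mobility_at_temperature()]) so that pKa values at different
#' nominal temperatures are compared at the *same* effective temperature,
#' removing the Joule-heating bias.
#'
#' @param T_actual actual temperatures (degC).
#' @param mu_ep matching electrophoretic mobilities (m^2 V^-1 s^-1).
#' @param degree polynomial degree; needs at least `degree + 1` points.
#' @param analyte_id,buffer_id optional labels carried into the model.
#' @param weights optional least-squares weights.
#' @return An object of class `"mobility_temp_model"` with elements
#'   `coefficients` (ascending powers), `domain` (temperature range covered),
#'   `degree`, and the underlying `lm` fit.
#' @export
fit_mobility_vs_temperature <- function(T_actual, mu_ep, degree = 2,
                                        analyte_id = NA, buffer_id = NA,
                                        weights = NULL) {
  if (length(T_actual) != length(mu_ep))
    stop("T_actual and mu_ep must have the same length")
  if (length(unique(T_actual)) < degree + 1)
    stop(sprintf("need at least %d distinct temperatures for degree %d",
                 degree + 1, degree))
  fit <- stats::lm(mu_ep ~ stats::poly(T_actual, degree, raw = TRUE),
                   weights = weights)
  structure(list(coefficients = unname(stats::coef(fit)),
                 domain = range(T_actual), degree = degree,
                 analyte_id = analyte_id, buffer_id = buffer_id, fit = fit),
            class = "mobility_temp_model")
}

#' @export
print.mobility_temp_model <- function(x, ...) {
  cat(sprintf("Mobility-temperature model: degree %d over %.1f-%.1f degC\n",
              x$degree, x$domain[1], x$domain[2]))
  cat("coefficients (ascending powers):",
      paste(signif(x$coefficients, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Read a mobility off a fitted temperature model
#'
#' Evaluates the polynomial at the requested temperatures of interest.
#' Requests outside the fitted temperature domain are honoured but flagged
#' as extrapolation.
#'
#' @param model a `"mobility_temp_model"`.
#' @param T_target temperatures of interest (degC), vectorized.
#' @return data.frame with columns `T_target`, `mu_ep`, `extrapolated`.
#' @export
mobility_at_temperature <- function(model, T_target) {
  stopifnot(inherits(model, "mobility_temp_model"))
  mu <- vapply(T_target, function(tt)
    sum(model$coefficients * tt^(seq_along(model$coefficients) - 1)),
    numeric(1))
  data.frame(T_target = T_target, mu_ep = mu,
             extrapolated = T_target < model$domain[1] |
               T_target > model$domain[2])
}

#' @export
predict.mobility_temp_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- newdata$T_target
  mobility_at_temperature(object, newdata)$mu_ep
}
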