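#' Average separation voltage under a linear voltage ramp
#'
#' At the start of a run the voltage rises linearly from zero to its nominal
#' value over the ramp time, so the time-averaged voltage experienced by a
#' species over its migration is lower than nominal:
#' `U_av = U_nom * (t_tot - 0.5 * t_ramp) / t_tot`.
#'
#' @param U_nom_kV nominal (programmed) voltage (kV).
#' @param t_tot_min migration time of the species (min).
#' @param t_ramp_min voltage ramp time (min).
#' @return Average voltage (kV), vectorized over its arguments.
#' @examples
#' average_voltage(30, 5, 0.17)  # 29.49 kV
#' @export
average_voltage <- function(U_nom_kV, t_tot_min, t_ramp_min) {
  if (any(t_ramp_min >= t_tot_min))
    stop("t_ramp_min must be smaller than the migration time")
  U_nom_kV * (t_tot_min - 0.5 * t_ramp_min) / t_tot_min
}

#' Electrophoretic mobilities from migration times
#'
#' Computes apparent, electroosmotic and electrophoretic mobilities for every
#' run in a table. Without correction the classical relation is used,
#' `mu_ep = (L_tot * L_eff / U_nom) * (1/t_tot - 1/t_eof)`. With
#' `ramping_correction = TRUE` each species' time is replaced by its
#' ramp-adjusted value `t - 0.5 * t_ramp` (the average-voltage correction
#' applied per species, since the analyte and the EOF marker spend different
#' fractions of their migration under the ramp):
#' `mu_ep = L_tot*L_eff/U_nom * (1/(t_tot - 0.5 t_ramp) - 1/(t_eof - 0.5 t_ramp))`.
#'
#' Mobilities are signed: `mu_ep > 0` exactly when the analyte is detected
#' before the EOF marker (for positive voltage). All values are SI
#' (m^2 V^-1 s^-1); times and voltages are taken from the run table in
#' minutes and kV and converted internally.
#'
#' @param runs a validated run table (see [run_table]).
#' @param geometry a [capillary_geometry].
#' @param ramping_correction logical; apply the per-species average-voltage
#'   correction for the linear voltage ramp.
#' @return `runs` with columns `mu_app`, `mu_eof`, `mu_ep`
#'   (m^2 V^-1 s^-1) and `ramping_corrected` appended.
#' @examples
#' geom <- capillary_geometry()
#' runs <- data.frame(analyte_id = "a", buffer_id = "b", pH = 7,
#'   T_coolant_C = 25, U_nom_kV = 30, t_ramp_min = 0.17,
#'   t_tot_min = 5, t_eof_min = 10, current_uA = 50, replicate = 1)
#' mobility(runs, geom)$mu_ep
#' mobility(runs, geom, ramping_correction = TRUE)$mu_ep
#' @export
mobility <- function(runs, geometry, ramping_correction = FALSE) {
  runs <- validate_run_table(runs)
  stopifnot(inherits(geometry, "capillary_geometry"))
  U <- runs$U_nom_kV * KV_TO_V
  offset <- if (ramping_correction) 0.5 * runs$t_ramp_min else 0
  t_tot <- (runs$t_tot_min - offset) * MIN_TO_S
  t_eof <- (runs$t_eof_min - offset) * MIN_TO_S
  Ll <- geometry$L_tot * geometry$L_eff
  runs$mu_app <- Ll / (U * t_tot)
  runs$mu_eof <- Ll / (U * t_eof)
  runs$mu_ep <- runs$mu_app - runs$mu_eof
  runs$ramping_corrected <- ramping_correction
  runs
}

#' Replicate-averaged electrophoretic mobilities
#'
#' Aggregates the per-run mobilities of [mobility()] over replicates within
#' each (analyte, buffer, pH, coolant temperature) cell, returning the mean
#' and sample standard deviation. Set `pool = TRUE` to skip aggregation and
#' keep every replicate as its own row (for pooled fitting).
#'
#' @inheritParams mobility
#' @param pool logical; if `TRUE`, return per-replicate rows unaggregated.
#' @return A data.frame with one row per cell (or per run when pooled) and
#'   columns `mu_ep`, `sd_mu_ep`, `n`, plus the mean current.
#' @export
mobility_summary <- function(runs, geometry, ramping_correction = FALSE,
                             pool = FALSE) {
  m <- mobility(runs, geometry, ramping_correction)
  if (pool) {
    m$sd_mu_ep <- NA_real_
    m$n <- 1L
    return(m)
  }
  key <- interaction(m$analyte_id, m$buffer_id, m$pH, m$T_coolant_C, drop = TRUE)
  parts <- split(m, key)
  out <- do.call(rbind, lapply(parts, function(g) data.frame(
    analyte_id = g$analyte_id[1], buffer_id = g$buffer_id[1],
    pH = g$pH[1], T_coolant_C = g$T_coolant_C[1],
    U_nom_kV = g$U_nom_kV[1], t_ramp_min = g$t_ramp_min[1],
    current_uA = mean(g$current_uA),
    mu_app = mean(g$mu_app), mu_eof = mean(g$mu_eof),
    mu_ep = mean(g$mu_ep),
    sd_mu_ep = if (nrow(g) > 1) stats::sd(g$mu_ep) else NA_real_,
    n = nrow(g),
    ramping_corrected = ramping_correction)))
  rownames(out) <- NULL
  out[order(out$analyte_id, out$buffer_id, out$T_coolant_C, out$pH), ]
}
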