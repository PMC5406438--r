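#' @name workflows
#' @title End-to-end screening and double-correction workflows
#'
#' @description
#' Two orchestrated analyses over a multi-system run table (systems are
#' distinguished by `analyte_id`, e.g. one label per host-guest pairing):
#'
#' * [run_screen()] — the fast two-values screen: per system, one
#'   partial-ionization and one full-ionization buffer give a closed-form
#'   pKa, and shifts are reported against a declared host-free reference
#'   system.
#' * [run_dcs()] — the double correction strategy: per system, pKa is fitted
#'   at several temperatures in three branches (non-corrected,
#'   ramping-corrected, fully corrected for ramping and Joule heating), each
#'   followed by a Van't Hoff analysis.
#'
#' Both return an `"ce_report"` carrying results plus provenance (input
#' digest, options, package version) so every number is traceable to its
#' input.
NULL

# md5 of a serialized object: provenance for reports
input_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE)
  unname(tools::md5sum(f))
}

new_ce_report <- function(kind, results, extra = list(), inputs = NULL,
                          options = list()) {
  structure(c(list(kind = kind, results = results), extra,
              list(provenance = list(
                inputs_digest = input_digest(inputs),
                options = options,
                package_version = as.character(utils::packageVersion("cepka"))))),
            class = "ce_report")
}

#' @export
print.ce_report <- function(x, ...) {
  cat(sprintf("CE analysis report (%s)\n", x$kind))
  if (is.data.frame(x$results)) print(x$results, row.names = FALSE)
  cat(sprintf("[inputs md5 %s]\n", substr(x$provenance$inputs_digest, 1, 8)))
  invisible(x)
}

#' Two-values pKa-shift screen
#'
#' @param runs a run table covering, per system (`analyte_id`), buffers at a
#'   partial-ionization pH and at a full-ionization pH.
#' @param geometry a [capillary_geometry].
#' @param reference `analyte_id` of the host-free reference system (an
#'   experimental designation, never inferred).
#' @param pH_full full-ionization pH; default the highest pH per system.
#' @param pH_partial partial-ionization pH; default the remaining pH whose
#'   mobility is closest to half the limiting mobility.
#' @param ramping_correction apply the voltage-ramp correction (default on).
#' @return A `"ce_report"` whose `results` has one row per system with
#'   columns `system`, `pKa`, `se`, `shift`, `se_shift`.
#' @rdname workflows
#' @export
run_screen <- function(runs, geometry, reference, pH_full = NULL,
                       pH_partial = NULL, ramping_correction = TRUE) {
  runs <- validate_run_table(runs)
  systems <- unique(runs$analyte_id)
  if (!reference %in% systems)
    stop(sprintf("reference system '%s' is not present in the run table",
                 reference))
  summ <- mobility_summary(runs, geometry, ramping_correction)
  fit_one <- function(sys) {
    g <- summ[summ$analyte_id == sys, ]
    p_full <- if (is.null(pH_full)) max(g$pH) else pH_full
    full <- g[g$pH == p_full, ]
    if (!nrow(full))
      stop(sprintf("system '%s' has no runs at the full-ionization pH %g",
                   sys, p_full))
    cand <- g[g$pH != p_full, ]
    p_part <- if (is.null(pH_partial))
      cand$pH[which.min(abs(abs(cand$mu_ep / full$mu_ep[1]) - 0.5))]
    else pH_partial
    part <- g[g$pH == p_part, ]
    if (!nrow(part))
      stop(sprintf("system '%s' has no runs at the partial-ionization pH %g",
                   sys, p_part))
    tvm_pka(part$pH[1], part$mu_ep[1], full$mu_ep[1],
            se_partial = part$sd_mu_ep[1] / sqrt(part$n[1]),
            se_anion = full$sd_mu_ep[1] / sqrt(full$n[1]))
  }
  fits <- lapply(systems, fit_one)
  names(fits) <- systems
  ref_fit <- fits[[reference]]
  res <- do.call(rbind, lapply(systems, function(sys) {
    sh <- pka_shift(fits[[sys]], ref_fit)
    data.frame(system = sys, pKa = fits[[sys]]$pKa, se = fits[[sys]]$se_pKa,
               shift = sh$delta_pKa, se_shift = sh$se)
  }))
  new_ce_report("tvm_screen", res, extra = list(fits = fits,
                                                reference = reference),
                inputs = runs,
                options = list(reference = reference,
                               ramping_correction = ramping_correction))
}

#' Double correction strategy
#'
#' @param runs a run table with, per system, runs at three or more coolant
#'   temperatures and recorded currents.
#' @param sumet a [sumet_parameters].
#' @param T_targets temperatures of interest for the fully corrected branch;
#'   default the coolant temperatures present.
#' @param degree polynomial degree of the mobility-temperature models.
#' @param w_inlet optional inlet weight override (see [actual_temperature()]).
#' @rdname workflows
#' @export
run_dcs <- function(runs, geometry, sumet = sumet_parameters(),
                    T_targets = NULL, degree = 2, w_inlet = NULL) {
  runs <- validate_run_table(runs)
  systems <- unique(runs$analyte_id)
  per_system <- lapply(systems, function(sys) {
    g <- runs[runs$analyte_id == sys, ]
    temps <- sort(unique(g$T_coolant_C))
    if (length(temps) < 3)
      stop(sprintf(
        "system '%s' covers only %d coolant temperature(s); DCS needs >= 3",
        sys, length(temps)))
    targets <- if (is.null(T_targets)) temps else T_targets

    branch_fit <- function(points) {
      # points: data.frame(temperature, pH, mu_ep) -> pKa per temperature
      do.call(rbind, lapply(sort(unique(points$temperature)), function(tt) {
        d <- points[points$temperature == tt, ]
        fit <- pka_fit(mu_ep ~ pH, d)
        data.frame(temperature = tt, pKa = fit$pKa, se = fit$se_pKa)
      }))
    }

    uncorr <- mobility_summary(g, geometry, ramping_correction = FALSE)
    ramp <- mobility_summary(g, geometry, ramping_correction = TRUE)
    b_non <- branch_fit(data.frame(temperature = uncorr$T_coolant_C,
                                   pH = uncorr$pH, mu_ep = uncorr$mu_ep))
    b_ramp <- branch_fit(data.frame(temperature = ramp$T_coolant_C,
                                    pH = ramp$pH, mu_ep = ramp$mu_ep))

    # fully corrected: ramping-corrected per-run mobilities re-referenced to
    # the temperatures of interest via per-buffer mobility-temperature models
    per_run <- run_temperature(g, geometry, sumet, w_inlet)
    per_run$mu_ep <- mobility(g, geometry, ramping_correction = TRUE)$mu_ep
    corrected <- do.call(rbind, lapply(unique(per_run$pH), function(p) {
      d <- per_run[per_run$pH == p, ]
      mdl <- fit_mobility_vs_temperature(d$T_actual, d$mu_ep, degree = degree,
                                         analyte_id = sys, buffer_id =
                                           d$buffer_id[1])
      at <- mobility_at_temperature(mdl, targets)
      data.frame(temperature = at$T_target, pH = p, mu_ep = at$mu_ep,
                 extrapolated = at$extrapolated)
    }))
    b_full <- branch_fit(corrected)

    vh <- function(b) if (nrow(b) >= 2) vant_hoff(b$temperature, b$pKa) else NULL
    list(system = sys,
         branches = list(non_corrected = b_non, ramping_corrected = b_ramp,
                         fully_corrected = b_full),
         vant_hoff = list(non_corrected = vh(b_non),
                          ramping_corrected = vh(b_ramp),
                          fully_corrected = vh(b_full)),
         any_extrapolated = any(corrected$extrapolated))
  })
  names(per_system) <- systems
  res <- do.call(rbind, lapply(per_system, function(s)
    do.call(rbind, lapply(names(s$branches), function(b)
      cbind(system = s$system, branch = b, s$branches[[b]])))))
  rownames(res) <- NULL
  new_ce_report("dcs", res, extra = list(systems = per_system),
                inputs = runs,
                options = list(T_targets = T_targets, degree = degree))
}

#' Convert a report to plain lists for JSON serialization
#'
#' @param report a `"ce_report"`.
#' @return A nested list of plain vectors and data.frames.
#' @export
report_to_list <- function(report) {
  stopifnot(inherits(report, "ce_report"))
  vh_list <- function(v) if (is.null(v)) NULL else
    list(dH_kJ_mol = v$dH, se_dH = v$se_dH, entropic_term = v$entropic_term,
         se_entropic = v$se_entropic, dS_J_mol_K = v$dS_SI,
         slope = v$slope, intercept = v$intercept, n = v$n)
  out <- list(kind = report$kind, results = report$results,
              provenance = report$provenance)
  if (!is.null(report$reference)) out$reference <- report$reference
  if (!is.null(report$systems))
    out$vant_hoff <- lapply(report$systems, function(s)
      lapply(s$vant_hoff, vh_list))
  out
}

#' Load a structured configuration file
#'
#' Reads a YAML configuration with optional sections `geometry`, `sumet`,
#' `fit` and `simulate`, and instantiates the corresponding package objects.
#'
#' @param path YAML file path.
#' @return A list with elements `geometry` ([capillary_geometry]), `sumet`
#'   ([sumet_parameters]), `scenario` ([simulation_scenario], if a
#'   `simulate` section is present), `fit` (options list), and the raw
#'   parsed config under `raw`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list(raw = cfg)
  out$geometry <- if (!is.null(cfg$geometry))
    do.call(capillary_geometry, cfg$geometry) else capillary_geometry()
  out$sumet <- if (!is.null(cfg$sumet))
    do.call(sumet_parameters, cfg$sumet) else sumet_parameters()
  out$fit <- if (!is.null(cfg$fit)) cfg$fit else list()
  if (!is.null(cfg$simulate)) {
    args <- cfg$simulate
    for (nm in c("pH_grid", "T_grid")) # YAML lists arrive as generic lists
      if (!is.null(args[[nm]])) args[[nm]] <- as.numeric(unlist(args[[nm]]))
    args$geometry <- out$geometry
    args$sumet <- out$sumet
    out$scenario <- do.call(simulation_scenario, args)
  }
  out
}
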