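#' Synthetic CE scenario
#'
#' Defines the ground truth for a simulated capillary-electrophoresis study
#' of a monoprotic acid (guest) in the presence of a neutral macrocyclic
#' host. The simulator assembles the full observational chain: deprotonation
#' and 1:1 complexation equilibria (fast exchange, one population-averaged
#' peak), temperature-dependent viscosity scaling of every mobility,
#' pH- and temperature-dependent run currents, Joule heating of the two
#' capillary sections, the linear voltage ramp, and multiplicative
#' migration-time noise.
#'
#' The defaults emulate a coumarin-like acid (pKa 4.13 at 25 degC, weakly
#' endothermic dissociation) with a cyclodextrin-like host at 10 mM binding
#' the protonated form ten times more strongly than the anion
#' (apparent-pKa shift +0.60 at 25 degC), exothermic complexation, counter-
#' electroosmotic analyte migration (the analyte is detected after the EOF
#' marker; mobilities are negative against a positive EOF), 30 kV with a
#' 0.17 min ramp, triplicate injections, six buffers, and 0.5 % relative
#' time noise.
#'
#' @param true_pKa pKa of the free guest at `T_ref`.
#' @param dH_acid standard dissociation enthalpy of the free guest (J/mol);
#'   positive = endothermic (pKa falls with temperature).
#' @param K_HA,K_A 1:1 binding constants of the protonated and deprotonated
#'   guest with the host at `T_ref` (1/M).
#' @param dH_complex complexation enthalpy applied to both binding constants
#'   (J/mol); negative = exothermic (binding weakens on heating).
#' @param host_conc host concentration (M).
#' @param mu_anion_free,mu_anion_complex limiting electrophoretic mobilities
#'   of the free and complexed anion (m^2 V^-1 s^-1, signed).
#' @param mu_eof_ref electroosmotic mobility at `T_ref`.
#' @param visc_coeff fractional mobility increase per degC (viscosity drop).
#' @param current_ref_uA plateau current at `T_ref` in the mid-pH buffer.
#' @param current_pH_coeff fractional current change per pH unit (buffers of
#'   different composition conduct differently).
#' @param current_T_coeff fractional current change per degC.
#' @param noise_cv coefficient of variation of migration times.
#' @param replicates injections per (pH, temperature) cell.
#' @param pH_grid buffer pH values.
#' @param T_grid nominal coolant temperatures (degC).
#' @param T_ref reference temperature for all temperature dependences.
#' @param geometry a [capillary_geometry].
#' @param sumet a [sumet_parameters] describing the Joule-heating response.
#' @param U_nom_kV nominal voltage (kV).
#' @param t_ramp_min voltage ramp time (min).
#' @param analyte_id,buffer_prefix labels used in the generated run table.
#' @param seed default seed used by [simulate_runs()].
#' @return An object of class `"simulation_scenario"`.
#' @export
simulation_scenario <- function(true_pKa = 4.13, dH_acid = 7400,
                                K_HA = 500, K_A = 50, dH_complex = -20000,
                                host_conc = 0.01,
                                mu_anion_free = -2.0e-8,
                                mu_anion_complex = -0.8e-8,
                                mu_eof_ref = 5.0e-8,
                                visc_coeff = 0.02,
                                current_ref_uA = 50,
                                current_pH_coeff = 0.03,
                                current_T_coeff = 0.02,
                                noise_cv = 0.005, replicates = 3,
                                pH_grid = c(3.0, 3.6, 4.2, 4.8, 5.4, 8.0),
                                T_grid = 25, T_ref = 25,
                                geometry = capillary_geometry(),
                                sumet = sumet_parameters(),
                                U_nom_kV = 30, t_ramp_min = 0.17,
                                analyte_id = "guest", buffer_prefix = "B",
                                seed = 1L) {
  stopifnot(K_HA >= 0, K_A >= 0, host_conc >= 0, noise_cv >= 0,
            replicates >= 1, inherits(geometry, "capillary_geometry"),
            inherits(sumet, "sumet_parameters"))
  structure(as.list(environment()), class = "simulation_scenario")
}

#' DCS validation scenario
#'
#' A [simulation_scenario] preset for validating the double correction
#' strategy: five coolant temperatures (15-55 degC) and noise-free migration
#' times, so that the remaining deviation of each analysis branch from the
#' known truth is purely the systematic ramping/Joule-heating error that the
#' corrections target.
#'
#' @param ... overrides passed to [simulation_scenario()].
#' @export
scenario_dcs <- function(...) {
  args <- list(T_grid = c(15, 25, 35, 45, 55), noise_cv = 0, ...)
  do.call(simulation_scenario, args[!duplicated(names(args), fromLast = TRUE)])
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat(sprintf("CE simulation scenario: true pKa %.3f (dH %.1f kJ/mol)\n",
              x$true_pKa, x$dH_acid / 1000))
  cat(sprintf("  host %.3g M, K_HA %.3g, K_A %.3g (dH_complex %.1f kJ/mol)\n",
              x$host_conc, x$K_HA, x$K_A, x$dH_complex / 1000))
  cat(sprintf("  apparent pKa at %g degC: %.3f\n", x$T_ref, apparent_pka(x)))
  cat(sprintf("  %d pH x %d T x %d replicates, noise CV %.2g%%\n",
              length(x$pH_grid), length(x$T_grid), x$replicates,
              100 * x$noise_cv))
  invisible(x)
}

# Van't Hoff temperature scaling of an equilibrium constant
.k_at_T <- function(K_ref, dH, T_C, T_ref) {
  K_ref * exp(-(dH / R_GAS) * (1 / (T_C + C_TO_K) - 1 / (T_ref + C_TO_K)))
}

#' Apparent pKa of the mixed free/complexed population
#'
#' With a 1:1 host binding both protonation states, the observed pKa of the
#' mixed population is shifted from the free-guest value by the competition
#' between the two binding equilibria:
#' `pKa_app = pKa_free + log10((1 + K_HA * c) / (1 + K_A * c))`.
#' Stronger binding of the protonated form (`K_HA > K_A`) stabilizes it and
#' raises the apparent pKa. All equilibrium constants and the free-guest pKa
#' are evaluated at the requested temperature via their Van't Hoff scaling.
#'
#' @param scn a [simulation_scenario].
#' @param T_C temperature (degC); default the scenario reference.
#' @return Apparent pKa (pH units), vectorized over `T_C`.
#' @examples
#' scn <- simulation_scenario(true_pKa = 4.13, K_HA = 500, K_A = 50,
#'                            host_conc = 0.01)
#' apparent_pka(scn)  # 4.13 + log10(6/1.5)
#' @export
apparent_pka <- function(scn, T_C = scn$T_ref) {
  stopifnot(inherits(scn, "simulation_scenario"))
  T_K <- T_C + C_TO_K
  pKa_free <- scn$true_pKa +
    scn$dH_acid / (R_GAS * log(10)) * (1 / T_K - 1 / (scn$T_ref + C_TO_K))
  K_HA <- .k_at_T(scn$K_HA, scn$dH_complex, T_C, scn$T_ref)
  K_A <- .k_at_T(scn$K_A, scn$dH_complex, T_C, scn$T_ref)
  pKa_free + log10((1 + K_HA * scn$host_conc) / (1 + K_A * scn$host_conc))
}

# population-average electrophoretic and electroosmotic mobilities at a
# given actual temperature and pH (noise-free physics)
.scenario_mobilities <- function(scn, pH, T_actual) {
  visc <- 1 + scn$visc_coeff * (T_actual - scn$T_ref)
  K_A <- .k_at_T(scn$K_A, scn$dH_complex, T_actual, scn$T_ref)
  x_A <- K_A * scn$host_conc / (1 + K_A * scn$host_conc)
  mu_anion_eff <- ((1 - x_A) * scn$mu_anion_free +
                     x_A * scn$mu_anion_complex) * visc
  f <- ionization_fraction(pH, apparent_pka(scn, T_actual))
  list(mu_ep = f * mu_anion_eff, mu_eof = scn$mu_eof_ref * visc,
       mu_anion_eff = mu_anion_eff)
}

.scenario_current <- function(scn, pH, T_coolant) {
  scn$current_ref_uA *
    (1 + scn$current_pH_coeff * (pH - mean(scn$pH_grid))) *
    (1 + scn$current_T_coeff * (T_coolant - scn$T_ref))
}

#' Simulate a table of CE runs
#'
#' Generates one run record per (pH, coolant temperature, replicate) of the
#' scenario design. For each run the plateau current is derived from the
#' buffer and coolant temperature, the actual electrolyte temperature from
#' the two-section Joule-heating model (single self-consistent pass), all
#' mobilities are evaluated at that actual temperature, and migration times
#' are inverted from the apparent mobilities including the ramp offset,
#' `t = L_tot * L_eff / (U * mu_app) + 0.5 * t_ramp`, before multiplicative
#' Gaussian noise is applied to the times. Output is deterministic for a
#' given seed.
#'
#' @param scn a [simulation_scenario].
#' @param seed integer seed; defaults to the scenario's own.
#' @return A validated run table (see [run_table]).
#' @export
simulate_runs <- function(scn, seed = scn$seed) {
  stopifnot(inherits(scn, "simulation_scenario"))
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
  }
  design <- expand.grid(replicate = seq_len(scn$replicates),
                        pH = scn$pH_grid, T_coolant = scn$T_grid,
                        KEEP.OUT.ATTRS = FALSE)
  geom <- scn$geometry
  Ll <- geom$L_tot * geom$L_eff
  U <- scn$U_nom_kV * KV_TO_V
  current <- .scenario_current(scn, design$pH, design$T_coolant)
  T_in <- sumet_section_temperature(design$T_coolant, scn$U_nom_kV, current,
                                    geom, scn$sumet, "noncooled")
  T_co <- sumet_section_temperature(design$T_coolant, scn$U_nom_kV, current,
                                    geom, scn$sumet, "cooled")
  T_act <- actual_temperature(T_in, T_co, geom)$T_actual
  mob <- .scenario_mobilities(scn, design$pH, T_act)
  mu_app <- mob$mu_eof + mob$mu_ep
  if (any(mu_app <= 0) || any(mob$mu_eof <= 0))
    stop("scenario yields a non-detectable species (non-positive apparent mobility)")
  t_tot <- Ll / (U * mu_app) / MIN_TO_S + 0.5 * scn$t_ramp_min
  t_eof <- Ll / (U * mob$mu_eof) / MIN_TO_S + 0.5 * scn$t_ramp_min
  if (scn$noise_cv > 0) {
    t_tot <- t_tot * (1 + stats::rnorm(nrow(design), 0, scn$noise_cv))
    t_eof <- t_eof * (1 + stats::rnorm(nrow(design), 0, scn$noise_cv))
  }
  runs <- data.frame(
    analyte_id = scn$analyte_id,
    buffer_id = paste0(scn$buffer_prefix, formatC(design$pH, format = "f",
                                                  digits = 1)),
    pH = design$pH, T_coolant_C = design$T_coolant,
    U_nom_kV = scn$U_nom_kV, t_ramp_min = scn$t_ramp_min,
    t_tot_min = t_tot, t_eof_min = t_eof,
    current_uA = current, replicate = design$replicate)
  validate_run_table(runs)
  runs
}

#' Gaussian-band template spectra for a coumarin-like acid
#'
#' Simple acid-form and base-form UV-vis templates on a shared grid: the
#' protonated form absorbs around 270 nm, the deprotonated form around
#' 300 nm, so the default analysis wavelength pair 270/300 nm gives a
#' well-separated beta contrast.
#'
#' The base-form band is scaled so that both forms have the same *total*
#' absorbance over the analysis pair (a two-point isosbestic condition).
#' Under that condition the absorbance ratio beta is exactly affine in the
#' ionization fraction and the Boltzmann fit of beta(pH) is unbiased; real
#' form pairs satisfy it only approximately, which adds a small systematic
#' distortion the sigmoid model absorbs into its plateaus.
#'
#' @param wavelengths shared wavelength grid (nm).
#' @param lambda_pair the two analysis wavelengths the templates are
#'   balanced for (nm).
#' @return A list with data.frames `acid` and `base`, each with columns
#'   `wavelength_nm` and `absorbance`.
#' @export
template_spectra <- function(wavelengths = seq(200, 600, by = 2),
                             lambda_pair = c(270, 300)) {
  baseline <- 0.02
  acid_band <- function(wl) 0.30 * exp(-(wl - 268)^2 / (2 * 16^2))
  base_band <- function(wl) exp(-(wl - 302)^2 / (2 * 20^2))
  scale <- sum(acid_band(lambda_pair)) / sum(base_band(lambda_pair))
  list(acid = data.frame(wavelength_nm = wavelengths,
                         absorbance = baseline + acid_band(wavelengths)),
       base = data.frame(wavelength_nm = wavelengths,
                         absorbance = baseline + scale * base_band(wavelengths)))
}

#' Simulate diode-array spectra across the pH grid
#'
#' For each pH of the scenario design, mixes the acid-form and base-form
#' template spectra in proportion to the ionization fraction at the
#' scenario's apparent pKa, `A(pH) = f * base + (1 - f) * acid`, adds
#' optional Gaussian noise, and truncates at zero absorbance.
#'
#' @param scn a [simulation_scenario].
#' @param acid_spectrum,base_spectrum data.frames with columns
#'   `wavelength_nm` and `absorbance` on an identical grid (see
#'   [template_spectra()]).
#' @param noise_sd additive absorbance noise (AU).
#' @param lambda_1,lambda_2 analysis wavelengths stored in the records.
#' @param T_C temperature at which the spectra are recorded (degC).
#' @param seed integer seed; defaults to the scenario's own.
#' @return A list of [spectral_record] objects, one per pH.
#' @export
simulate_spectra <- function(scn, acid_spectrum = template_spectra()$acid,
                             base_spectrum = template_spectra()$base,
                             noise_sd = 0, lambda_1 = 270, lambda_2 = 300,
                             T_C = scn$T_ref, seed = scn$seed) {
  stopifnot(inherits(scn, "simulation_scenario"))
  if (!identical(acid_spectrum$wavelength_nm, base_spectrum$wavelength_nm))
    stop("acid and base template spectra must share one wavelength grid")
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
  }
  pKa_app <- apparent_pka(scn, T_C)
  lapply(scn$pH_grid, function(p) {
    f <- ionization_fraction(p, pKa_app)
    a <- f * base_spectrum$absorbance + (1 - f) * acid_spectrum$absorbance
    if (noise_sd > 0)
      a <- a + stats::rnorm(length(a), 0, noise_sd)
    spectral_record(p, acid_spectrum$wavelength_nm, pmax(a, 0),
                    lambda_1, lambda_2)
  })
}
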