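# shared fixtures, built in code at test time

default_geom <- capillary_geometry(0.60, 0.50, 0.04, 50e-6)

# one well-formed run record as a data.frame row; fields overridable
make_run <- function(...) {
  base <- data.frame(analyte_id = "a", buffer_id = "b", pH = 4.6,
                     T_coolant_C = 25, U_nom_kV = 30, t_ramp_min = 0.17,
                     t_tot_min = 6, t_eof_min = 4, current_uA = 50,
                     replicate = 1L)
  over <- list(...)
  base[names(over)] <- over
  base
}

# random valid run tables for round-trip properties
random_run_table <- function(n, seed) {
  set.seed(seed)
  t_eof <- runif(n, 2, 12)
  data.frame(analyte_id = sample(c("4HC", "CT", "CF"), n, replace = TRUE),
             buffer_id = paste0("B", sample(1:4, n, replace = TRUE)),
             pH = round(runif(n, 2.5, 9), 2),
             T_coolant_C = sample(c(15, 25, 35, 45, 55), n, replace = TRUE),
             U_nom_kV = sample(c(-30, 25, 30), n, replace = TRUE),
             t_ramp_min = round(runif(n, 0, 0.2), 3),
             t_tot_min = t_eof + runif(n, 0.5, 6),
             t_eof_min = t_eof,
             current_uA = round(runif(n, 20, 90), 1),
             replicate = sample(1:3, n, replace = TRUE))
}

# reference pKa(T) series for the four coumarin + methylated-beta-CD systems
# (fully corrected determinations at 15-55 degC) with their published
# dissociation enthalpies (kJ/mol) and dimensionless entropic terms
corrected_pka_series <- list(
  `4HC+DMbCD` = list(T_C = c(15, 25, 35, 45, 55),
                     pKa = c(5.33, 5.23, 5.12, 5.00, 4.88),
                     dH = 20.4, entropic = -3.8),
  `CT+DMbCD` = list(T_C = c(15, 25, 35, 45, 55),
                    pKa = c(5.21, 5.18, 5.15, 5.08, 5.01),
                    dH = 9.0, entropic = -8.3),
  `4HC+TMbCD` = list(T_C = c(15, 25, 35, 45, 55),
                     pKa = c(4.77, 4.64, 4.54, 4.46, 4.38),
                     dH = 17.4, entropic = -3.7),
  `CT+TMbCD` = list(T_C = c(15, 25, 35, 45, 55),
                    pKa = c(4.48, 4.47, 4.45, 4.44, 4.42),
                    dH = 2.7, entropic = -9.2))

# DCS validation: simulate once per test run and cache
dcs_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      scn <- scenario_dcs()
      runs <- simulate_runs(scn)
      rep <- run_dcs(runs, scn$geometry, scn$sumet)
      cache <<- list(scn = scn, runs = runs, report = rep,
                     truth = apparent_pka(scn, sort(unique(runs$T_coolant_C))))
    }
    cache
  }
})
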