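screen_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      hostK <- list(aCD = c(60, 55), bCD = c(220, 60), HPbCD = c(230, 65),
                    MebCD = c(280, 60), DMbCD = c(500, 50), TMbCD = c(160, 70))
      runs <- rbind(
        simulate_runs(simulation_scenario(host_conc = 0, analyte_id = "ref",
                                          seed = 100)),
        do.call(rbind, lapply(seq_along(hostK), function(i)
          simulate_runs(simulation_scenario(
            K_HA = hostK[[i]][1], K_A = hostK[[i]][2],
            analyte_id = names(hostK)[i], seed = 100 + i)))))
      cache <<- list(runs = runs, hostK = hostK)
    }
    cache
  }
})

test_that("the two-values screen estimates shifts for every host system", {
  fx <- screen_fixture()
  rep <- run_screen(fx$runs, default_geom, reference = "ref")
  expect_s3_class(rep, "ce_report")
  expect_equal(nrow(rep$results), length(fx$hostK) + 1)
  # the reference system shifts by exactly zero against itself
  expect_equal(rep$results$shift[rep$results$system == "ref"], 0)
  # estimated shifts track the scenario ground truth
  for (h in names(fx$hostK)) {
    truth <- log10((1 + fx$hostK[[h]][1] * 0.01) /
                     (1 + fx$hostK[[h]][2] * 0.01))
    got <- rep$results$shift[rep$results$system == h]
    expect_lt(abs(got - truth), 0.1)
  }
  # reproducible: same inputs give identical results
  rep2 <- run_screen(fx$runs, default_geom, reference = "ref")
  expect_identical(rep$results, rep2$results)
  expect_error(run_screen(fx$runs, default_geom, reference = "nope"),
               "reference system")
})

test_that("screen shift matrix reproduces worked shift values from pKa pairs", {
  # applying the shift operation to a published-style pKa matrix: each column
  # differenced against its host-free row
  pKa <- rbind(reference = c(4.13, 4.38, 4.25, 4.16),
               DMbCD = c(5.08, 5.00, 5.03, 5.20),
               TMbCD = c(4.54, 4.43, 4.29, 4.76))
  shifts <- sweep(pKa, 2, pKa["reference", ])
  expect_equal(unname(shifts["DMbCD", ]), c(0.95, 0.62, 0.78, 1.04))
  expect_equal(unname(shifts["TMbCD", ]), c(0.41, 0.05, 0.04, 0.60))
  expect_equal(max(shifts), 1.04)
})

test_that("DCS branches coincide when there is no ramp and no heating", {
  scn <- scenario_dcs(t_ramp_min = 0, sumet = sumet_parameters(0, 0))
  # degree 4 over five temperatures: the mobility-temperature model
  # interpolates, so re-referencing at the coolant temperatures is exact
  rep <- run_dcs(simulate_runs(scn), scn$geometry, scn$sumet, degree = 4)
  res <- rep$results
  non <- res$pKa[res$branch == "non_corrected"]
  ram <- res$pKa[res$branch == "ramping_corrected"]
  ful <- res$pKa[res$branch == "fully_corrected"]
  expect_equal(ram, non, tolerance = 1e-9)
  expect_equal(ful, non, tolerance = 1e-6)
})

test_that("DCS corrections act in opposite directions and reduce bias", {
  fx <- dcs_fixture()
  res <- fx$report$results
  non <- res$pKa[res$branch == "non_corrected"]
  ram <- res$pKa[res$branch == "ramping_corrected"]
  ful <- res$pKa[res$branch == "fully_corrected"]
  expect_true(all(ram < non))  # ramping correction lowers pKa
  expect_true(all(ful > ram))  # thermal correction raises pKa
  expect_true(all(abs(ful - fx$truth) < abs(non - fx$truth)))
  # Van't Hoff blocks exist for every branch
  vh <- fx$report$systems[[1]]$vant_hoff
  expect_named(vh, c("non_corrected", "ramping_corrected", "fully_corrected"))
  expect_s3_class(vh$fully_corrected, "vant_hoff")
})

test_that("DCS rejects systems with too few temperatures and missing currents", {
  scn <- simulation_scenario(T_grid = c(25, 35), noise_cv = 0)
  expect_error(run_dcs(simulate_runs(scn), scn$geometry, scn$sumet),
               "guest.*>= 3")
  fx <- dcs_fixture()
  runs <- fx$runs
  runs$current_uA <- NA
  expect_error(run_dcs(runs, fx$scn$geometry, fx$scn$sumet), "missing")
})

test_that("reports serialize deterministically", {
  fx <- screen_fixture()
  json <- function() jsonlite::toJSON(report_to_list(
    run_screen(fx$runs, default_geom, reference = "ref")),
    auto_unbox = TRUE, digits = NA)
  expect_identical(json(), json())
})

test_that("configuration files instantiate geometry, SUMET and scenarios", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "geometry:", "  L_tot: 0.8", "  L_eff: 0.7", "  L_inlet: 0.05",
    "sumet:", "  kappa_noncooled: 1.5", "  kappa_cooled: 0.3",
    "fit:", "  degree: 2",
    "simulate:", "  true_pKa: 4.2", "  noise_cv: 0", "  seed: 5",
    "  pH_grid: [3.0, 4.0, 5.0, 8.0]", "  T_grid: [25]"), f)
  cfg <- load_config(f)
  expect_equal(cfg$geometry$L_tot, 0.8)
  expect_equal(cfg$sumet$kappa_cooled, 0.3)
  expect_equal(cfg$scenario$true_pKa, 4.2)
  expect_equal(cfg$scenario$pH_grid, c(3, 4, 5, 8))
  expect_identical(cfg$scenario$geometry$L_eff, 0.7)
})

test_that("the CLI drives a simulate -> mobility -> fit -> thermo round trip", {
  cfg_f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("simulate:", "  seed: 3", "  noise_cv: 0.005"), cfg_f)
  runs_f <- withr::local_tempfile(fileext = ".csv")
  cepka_cli(c("simulate", "--config", cfg_f, "--out", runs_f))
  runs <- read_run_table(runs_f)
  expect_equal(nrow(runs), 18)  # 6 pH x 3 replicates

  mob_f <- withr::local_tempfile(fileext = ".csv")
  cepka_cli(c("mobility", "--runs", runs_f, "--out", mob_f))
  mob <- read.csv(mob_f)
  expect_equal(nrow(mob), 36)  # both correction states
  expect_true(all(c(FALSE, TRUE) %in% mob$ramping_corrected))

  fit_f <- withr::local_tempfile(fileext = ".json")
  cepka_cli(c("fit-classical", "--runs", runs_f, "--out", fit_f))
  rec <- jsonlite::read_json(fit_f, simplifyVector = TRUE)
  expect_equal(rec$guest$method, "classical")
  expect_lt(abs(rec$guest$pKa - 4.732), 0.1)
  expect_match(rec$guest$inputs_digest, "^[0-9a-f]{32}$")

  vh_f <- withr::local_tempfile(fileext = ".csv")
  s <- corrected_pka_series[["4HC+DMbCD"]]
  write.csv(data.frame(system = "s1", T_C = s$T_C, pKa = s$pKa), vh_f,
            row.names = FALSE)
  out_f <- withr::local_tempfile(fileext = ".json")
  cepka_cli(c("vant-hoff", "--table", vh_f, "--out", out_f))
  vh <- jsonlite::read_json(out_f, simplifyVector = TRUE)
  expect_equal(round(vh$s1$dH_kJ_mol, 1), 20.4)

  expect_error(cepka_cli(character(0)), "usage")
  expect_error(cepka_cli(c("frobnicate")), "unknown subcommand")
})

test_that("the CLI screen and spectral subcommands emit JSON reports", {
  fx <- screen_fixture()
  runs_f <- withr::local_tempfile(fileext = ".csv")
  write_run_table(fx$runs, runs_f)
  out_f <- withr::local_tempfile(fileext = ".json")
  cepka_cli(c("screen", "--runs", runs_f, "--reference", "ref",
              "--out", out_f))
  rep <- jsonlite::read_json(out_f, simplifyVector = TRUE)
  expect_equal(rep$kind, "tvm_screen")
  expect_true("DMbCD" %in% rep$results$system)

  spec_f <- withr::local_tempfile(fileext = ".csv")
  scn <- simulation_scenario(noise_cv = 0)
  write_spectra(simulate_spectra(scn, noise_sd = 0), spec_f)
  sp_out <- withr::local_tempfile(fileext = ".json")
  cepka_cli(c("fit-spectral", "--spectra", spec_f, "--out", sp_out))
  sp <- jsonlite::read_json(sp_out, simplifyVector = TRUE)
  expect_equal(sp$method, "spectral")
  expect_equal(sp$pKa, apparent_pka(scn), tolerance = 1e-4)
})
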