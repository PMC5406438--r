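test_that("classical fit recovers exact sigmoid parameters", {
  pH <- c(3.0, 4.0, 4.5, 5.0, 6.5)
  d <- data.frame(pH = pH, mu_ep = ionization_fraction(pH, 4.50) * -2.0e-8)
  fit <- pka_fit(mu_ep ~ pH, d)
  expect_equal(fit$pKa, 4.50, tolerance = 1e-6)
  expect_equal(fit$mu_anion, -2.0e-8, tolerance = 1e-6)
  expect_identical(fit$method, "classical")
  expect_equal(fit$n_points, 5L)
  expect_equal(unname(coef(fit)["pKa"]), fit$pKa)
  expect_equal(residuals(fit), rep(0, 5), tolerance = 1e-13)
  expect_equal(predict(fit, 4.50), fit$mu_anion / 2, tolerance = 1e-6)
})

test_that("classical fit guards degenerate and under-determined input", {
  expect_error(pka_fit(mu_ep ~ pH, data.frame(pH = c(3, 5), mu_ep = c(0, -1e-8))),
               "at least 3 distinct")
  expect_error(pka_fit(mu_ep ~ pH,
                       data.frame(pH = c(3, 4, 5), mu_ep = c(0, 0, 0))),
               "degenerate")
  pH <- c(6, 7, 8, 9)  # all beyond the transition
  d <- data.frame(pH = pH, mu_ep = ionization_fraction(pH, 4.0) * -2e-8)
  expect_warning(pka_fit(mu_ep ~ pH, d), "bracket")
})

test_that("classical fit is unbiased under mobility noise (Monte Carlo)", {
  set.seed(42)
  pH <- c(3.0, 3.8, 4.3, 4.8, 5.3, 6.5)
  truth <- 4.50
  mu <- ionization_fraction(pH, truth) * -2.0e-8
  est <- replicate(200, {
    d <- data.frame(pH = pH, mu_ep = mu + rnorm(length(pH), 0, 0.01 * 2e-8))
    pka_fit(mu_ep ~ pH, d)$pKa
  })
  se_mean <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - truth), 3 * se_mean + 1e-3)
})

test_that("two-values method matches its closed form and propagates error", {
  # half-ionization: the partial point sits at the inflection
  expect_equal(tvm_pka(4.6, -1.0e-8, -2.0e-8)$pKa, 4.6)
  # hand evaluation: 4.6 + log10((-2 + 0.4) / -0.4) = 4.6 + log10(4)
  fit <- tvm_pka(4.6, -0.4e-8, -2.0e-8)
  expect_equal(fit$pKa, 4.6 + log10(4))
  expect_equal(fit$pKa, 5.2021, tolerance = 1e-4)
  expect_identical(fit$method, "tvm")
  expect_identical(fit$n_points, 2L)
  # propagated SE shrinks with the replicate SDs
  se1 <- tvm_pka(4.6, -0.4e-8, -2.0e-8, 1e-10, 1e-10)$se_pKa
  se2 <- tvm_pka(4.6, -0.4e-8, -2.0e-8, 5e-11, 5e-11)$se_pKa
  expect_equal(se2, se1 / 2)
  expect_gt(se1, 0)
})

test_that("two-values method rejects fully ionized or neutral partial points", {
  expect_error(tvm_pka(4.6, -2.0e-8, -2.0e-8), "outside \\(0, 1\\)")
  expect_error(tvm_pka(4.6, -2.5e-8, -2.0e-8), "outside \\(0, 1\\)")
  expect_error(tvm_pka(4.6, 0.4e-8, -2.0e-8), "same sign")
})

test_that("two-values method exactly inverts the sigmoid mobility model", {
  grid <- expand.grid(pKa = seq(2, 10, by = 0.5), pH = seq(2, 10, by = 0.5))
  mu_anion <- -2.0e-8
  for (i in seq_len(nrow(grid))) {
    f <- ionization_fraction(grid$pH[i], grid$pKa[i])
    if (f < 1e-12 || f > 1 - 1e-12) next
    got <- tvm_pka(grid$pH[i], f * mu_anion, mu_anion)$pKa
    expect_equal(got, grid$pKa[i], tolerance = 1e-6)
  }
})

test_that("classical and two-values estimates coincide on noiseless data", {
  pH <- c(3.2, 4.0, 4.6, 5.2, 8.0)
  mu <- ionization_fraction(pH, 4.37) * -1.8e-8
  cls <- pka_fit(mu_ep ~ pH, data.frame(pH = pH, mu_ep = mu))
  tv <- tvm_pka(4.6, mu[pH == 4.6], -1.8e-8)
  expect_lt(abs(cls$pKa - tv$pKa), 1e-6)
})

test_that("beta parameter handles boundaries, interpolation and degeneracy", {
  rec <- function(a270, a300)
    spectral_record(4, c(250, 270, 300, 320), c(0.05, a270, a300, 0.05))
  expect_equal(beta_parameter(rec(0.2, 0.2)), 0.5)
  expect_equal(beta_parameter(rec(0.2, 0)), 1)
  expect_equal(beta_parameter(rec(0.30, 0.10)), 0.75)
  # interpolation between grid points
  rec2 <- spectral_record(4, c(260, 280, 290, 310), c(0.1, 0.3, 0.3, 0.1))
  expect_equal(beta_parameter(rec2), 0.5)  # symmetric bands
  rec0 <- spectral_record(4, c(250, 270, 300, 320), c(0.1, 0, 0, 0.1))
  expect_error(beta_parameter(rec0), "degenerate")
})

test_that("beta stays within [0, 1] for valid spectra", {
  set.seed(9)
  wl <- seq(200, 600, by = 4)
  for (i in 1:20) {
    a <- abs(rnorm(length(wl), 0.2, 0.1))
    b <- beta_parameter(spectral_record(4, wl, a))
    expect_gte(b, 0); expect_lte(b, 1)
  }
})

test_that("spectral Boltzmann fit recovers the inflection point", {
  pH <- c(3.0, 3.8, 4.4, 5.0, 6.0)
  beta <- 0.83 + (0.21 - 0.83) * ionization_fraction(pH, 4.37)
  fit <- pka_fit(beta ~ pH, data.frame(pH = pH, beta = beta),
                 method = "spectral")
  expect_equal(fit$pKa, 4.37, tolerance = 1e-6)
  expect_true(is.na(fit$mu_anion))
  expect_identical(fit$method, "spectral")
  expect_error(pka_fit(beta ~ pH, data.frame(pH = pH[1:3], beta = beta[1:3]),
                       method = "spectral"), "at least 4 distinct")
})

test_that("spectral fit is invariant to a pH-independent gain", {
  pH <- c(3.0, 3.8, 4.4, 5.0, 6.0, 7.5)
  tmpl <- template_spectra()
  base_fit <- NULL
  for (gain in c(1, 2.5)) {
    beta <- vapply(pH, function(p) {
      f <- ionization_fraction(p, 4.37)
      mix <- gain * (f * tmpl$base$absorbance + (1 - f) * tmpl$acid$absorbance)
      beta_parameter(spectral_record(p, tmpl$base$wavelength_nm, mix))
    }, numeric(1))
    fit <- pka_fit(beta ~ pH, data.frame(pH = pH, beta = beta),
                   method = "spectral")
    if (is.null(base_fit)) base_fit <- fit else
      expect_equal(fit$pKa, base_fit$pKa, tolerance = 1e-9)
  }
})

test_that("fit options expose a free baseline and a free slope", {
  pH <- c(3.0, 3.8, 4.4, 5.0, 6.0)
  mu <- -0.2e-8 + ionization_fraction(pH, 4.5) * -1.8e-8
  fb <- pka_fit(mu_ep ~ pH, data.frame(pH = pH, mu_ep = mu),
                free_baseline = TRUE)
  expect_equal(fb$pKa, 4.5, tolerance = 1e-6)
  expect_equal(unname(coef(fb)["mu_neutral"]), -0.2e-8, tolerance = 1e-6)

  beta <- 0.8 + (0.2 - 0.8) * ionization_fraction(pH, 4.5, slope = 1.3)
  fs <- pka_fit(beta ~ pH, data.frame(pH = pH, beta = beta),
                method = "spectral", free_slope = TRUE)
  expect_equal(fs$pKa, 4.5, tolerance = 1e-5)
  expect_equal(unname(coef(fs)["slope"]), 1.3, tolerance = 1e-4)
})
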