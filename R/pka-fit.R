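#' Ionization fraction of a monoprotic acid
#'
#' Henderson-Hasselbalch fraction of the deprotonated form,
#' `f = 10^(-pKa) / (10^(-pKa) + 10^(-pH)) = 1 / (1 + 10^(pKa - pH))`.
#'
#' @param pH buffer pH, vectorized.
#' @param pKa acid dissociation exponent.
#' @param slope optional Hill-type slope factor (1 = Henderson-Hasselbalch).
#' @return Fraction in `(0, 1)`.
#' @export
ionization_fraction <- function(pH, pKa, slope = 1) {
  1 / (1 + 10^(slope * (pKa - pH)))
}

#' Fit a pKa from a sigmoid titration curve
#'
#' Fits the pH at the inflection point of an observable that follows the
#' monoprotic ionization equilibrium. Two observables are supported:
#'
#' * `method = "classical"`: the observable is the electrophoretic mobility,
#'   `mu_ep(pH) = f(pH, pKa) * mu_anion`, where `f` is the ionization
#'   fraction and `mu_anion` the limiting mobility of the fully deprotonated
#'   form (the neutral form has zero mobility; set `free_baseline = TRUE` to
#'   free a nonzero neutral-form plateau).
#' * `method = "spectral"`: the observable is the absorbance ratio
#'   `beta = A1/(A1 + A2)` (see [beta_parameter()]), fitted as a Boltzmann
#'   sigmoid with both plateaus free:
#'   `beta(pH) = beta_acid + (beta_base - beta_acid) * f(pH, pKa)`.
#'
#' The nonlinear least-squares fit uses the Levenberg-Marquardt algorithm
#' with data-driven starting values (pKa starts at the pH of the
#' half-transition point); on non-convergence the start is perturbed
#' deterministically up to `max_restarts` times.
#'
#' @param formula observable ~ pH, e.g. `mu_ep ~ pH` or `beta ~ pH`.
#' @param data data.frame holding the formula variables.
#' @param method `"classical"` (mobility) or `"spectral"` (beta ratio).
#' @param weights optional least-squares weights (e.g. inverse variances of
#'   replicate-averaged mobilities).
#' @param free_baseline classical method only: free a nonzero mobility for
#'   the neutral form instead of fixing it at zero.
#' @param free_slope spectral method only: free a Hill-type slope factor
#'   instead of the fixed Henderson-Hasselbalch slope.
#' @param start optional named list of starting values overriding the
#'   data-driven defaults.
#' @param max_restarts maximum number of perturbed restarts on
#'   non-convergence.
#' @return An object of class `"pka_fit"` with components `pKa`, `se_pKa`,
#'   `coefficients`, `mu_anion` (classical only), `method`, `n_points`, the
#'   underlying `nls` fit and the model data. Supports `print()`,
#'   `summary()`, `coef()`, `vcov()`, `predict()`, `residuals()`,
#'   `fitted()`, `plot()` and `simulate()`.
#' @examples
#' pH <- c(3, 4, 4.5, 5, 6.5)
#' d <- data.frame(pH = pH, mu_ep = ionization_fraction(pH, 4.5) * -2e-8)
#' fit <- pka_fit(mu_ep ~ pH, d)
#' coef(fit)
#' @export
pka_fit <- function(formula, data, method = c("classical", "spectral"),
                    weights = NULL, free_baseline = FALSE, free_slope = FALSE,
                    start = NULL, max_restarts = 5) {
  method <- match.arg(method)
  mf <- stats::model.frame(formula, data)
  y <- mf[[1]]
  pH <- mf[[2]]
  ok <- stats::complete.cases(y, pH)
  y <- y[ok]; pH <- pH[ok]
  if (!is.null(weights)) weights <- weights[ok]
  n_distinct <- length(unique(pH))
  min_pts <- switch(method, classical = if (free_baseline) 4 else 3,
                    spectral = if (free_slope) 5 else 4)
  if (n_distinct < min_pts)
    stop(sprintf("%s fit needs at least %d distinct pH values, got %d",
                 method, min_pts, n_distinct))
  if (method == "classical" && max(abs(y)) == 0)
    stop("degenerate data: all mobilities are zero")

  spec <- pka_model_spec(method, free_baseline, free_slope)
  s0 <- pka_start_values(method, pH, y, free_baseline, free_slope)
  if (!is.null(start)) s0[names(start)] <- start

  df <- data.frame(pH = pH, y = y,
                   .w = if (is.null(weights)) rep(1, length(y)) else weights)
  fit <- NULL
  last_err <- NULL
  # deterministic start perturbations, alternating around the data-driven start
  jitter_seq <- c(0, 0.4, -0.4, 0.8, -0.8, 1.2)[seq_len(max_restarts + 1)]
  for (j in jitter_seq) {
    sj <- s0
    sj$pKa <- s0$pKa + j
    fit <- tryCatch(
      minpack.lm::nlsLM(spec$formula, data = df, start = sj, weights = .w,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) { last_err <<- e; NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("pKa fit did not converge after ", max_restarts, " restarts: ",
         conditionMessage(last_err))

  cf <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  if (!any(pH < cf[["pKa"]]) || !any(pH > cf[["pKa"]]))
    warning("pH values do not bracket the fitted pKa; ",
            "the transition is not covered on both sides")
  structure(list(
    pKa = cf[["pKa"]], se_pKa = unname(se["pKa"]),
    mu_anion = if (method == "classical") cf[["mu_anion"]] else NA_real_,
    se_mu_anion = if (method == "classical") unname(se["mu_anion"]) else NA_real_,
    coefficients = cf, method = method, n_points = length(pH),
    free_baseline = free_baseline, free_slope = free_slope,
    data = df, fit = fit, call = match.call()),
    class = "pka_fit")
}

# model formulas and starting values for the two sigmoid observables
pka_model_spec <- function(method, free_baseline, free_slope) {
  f <- if (method == "classical") {
    if (free_baseline)
      y ~ mu_neutral + (mu_anion - mu_neutral) / (1 + 10^(pKa - pH))
    else
      y ~ mu_anion / (1 + 10^(pKa - pH))
  } else {
    if (free_slope)
      y ~ beta_acid + (beta_base - beta_acid) / (1 + 10^(slope * (pKa - pH)))
    else
      y ~ beta_acid + (beta_base - beta_acid) / (1 + 10^(pKa - pH))
  }
  list(formula = f)
}

pka_start_values <- function(method, pH, y, free_baseline, free_slope) {
  if (method == "classical") {
    i_max <- which.max(abs(y))
    mu_anion0 <- y[i_max]
    pKa0 <- pH[which.min(abs(abs(y) - abs(mu_anion0) / 2))]
    s <- list(pKa = pKa0, mu_anion = mu_anion0)
    if (free_baseline) s$mu_neutral <- 0
  } else {
    acid0 <- y[which.min(pH)]
    base0 <- y[which.max(pH)]
    pKa0 <- pH[which.min(abs(y - (acid0 + base0) / 2))]
    s <- list(pKa = pKa0, beta_acid = acid0, beta_base = base0)
    if (free_slope) s$slope <- 1
  }
  s
}

#' Two-values method: closed-form pKa from two mobilities
#'
#' Computes the pKa of a monoprotic acid from a single partially ionized
#' mobility and the limiting mobility of the fully ionized (anionic) form:
#' `pKa = pH + log10((mu_anion - mu_partial) / mu_partial)`. This is the
#' exact algebraic inverse of the sigmoid mobility model and needs only two
#' buffers (one giving partial, one giving total ionization), which makes it
#' suited to fast screening of host-induced pKa shifts.
#'
#' The standard error, when replicate standard deviations are supplied, is
#' obtained by first-order propagation through the closed form.
#'
#' @param pH_partial pH of the partial-ionization buffer.
#' @param mu_partial electrophoretic mobility at `pH_partial`
#'   (m^2 V^-1 s^-1, signed).
#' @param mu_anion limiting mobility of the fully ionized form (same sign).
#' @param se_partial,se_anion optional standard deviations of the two
#'   mobilities for error propagation.
#' @return An object of class `"pka_fit"` with `method = "tvm"` and
#'   `n_points = 2`.
#' @examples
#' tvm_pka(4.6, -0.4e-8, -2.0e-8)  # pKa = 4.6 + log10(4)
#' @export
tvm_pka <- function(pH_partial, mu_partial, mu_anion,
                    se_partial = NULL, se_anion = NULL) {
  if (sign(mu_partial) != sign(mu_anion) || mu_partial == 0)
    stop("mu_partial and mu_anion must be non-zero and of the same sign")
  ratio <- mu_partial / mu_anion
  if (ratio <= 0 || ratio >= 1)
    stop("mu_partial/mu_anion = ", signif(ratio, 4), " lies outside (0, 1): ",
         "the analyte appears fully ionized or fully neutral at pH ",
         pH_partial)
  pKa <- pH_partial + log10((mu_anion - mu_partial) / mu_partial)
  se <- NA_real_
  if (!is.null(se_partial) && !is.null(se_anion)) {
    D <- mu_anion - mu_partial
    d_part <- (-1 / D - 1 / mu_partial) / log(10)
    d_anion <- (1 / D) / log(10)
    se <- sqrt((d_part * se_partial)^2 + (d_anion * se_anion)^2)
  }
  structure(list(
    pKa = pKa, se_pKa = se, mu_anion = mu_anion, se_mu_anion =
      if (is.null(se_anion)) NA_real_ else se_anion,
    coefficients = c(pKa = pKa, mu_anion = mu_anion),
    method = "tvm", n_points = 2L,
    data = data.frame(pH = pH_partial, y = mu_partial),
    fit = NULL, call = match.call()),
    class = "pka_fit")
}

#' @export
print.pka_fit <- function(x, ...) {
  cat(sprintf("pKa estimate (%s method)\n", x$method))
  cat(sprintf("  pKa = %.3f", x$pKa))
  if (is.finite(x$se_pKa)) cat(sprintf(" (SE %.3f)", x$se_pKa))
  cat(sprintf("   [%d point%s]\n", x$n_points, if (x$n_points > 1) "s" else ""))
  if (x$method != "spectral" && is.finite(x$mu_anion))
    cat(sprintf("  limiting anion mobility = %.4g m^2/V/s\n", x$mu_anion))
  invisible(x)
}

#' @export
coef.pka_fit <- function(object, ...) object$coefficients

#' @export
vcov.pka_fit <- function(object, ...) {
  if (!is.null(object$fit)) return(stats::vcov(object$fit))
  v <- matrix(NA_real_, 2, 2, dimnames = list(c("pKa", "mu_anion"),
                                              c("pKa", "mu_anion")))
  v["pKa", "pKa"] <- object$se_pKa^2
  v["mu_anion", "mu_anion"] <- object$se_mu_anion^2
  v
}

#' @export
summary.pka_fit <- function(object, ...) {
  tab <- if (!is.null(object$fit)) summary(object$fit)$coefficients else
    cbind(Estimate = object$coefficients,
          `Std. Error` = c(object$se_pKa, object$se_mu_anion))
  structure(list(method = object$method, pKa = object$pKa,
                 se_pKa = object$se_pKa, n_points = object$n_points,
                 coefficients = tab,
                 sigma = if (!is.null(object$fit)) summary(object$fit)$sigma
                         else NA_real_),
            class = "summary.pka_fit")
}

#' @export
print.summary.pka_fit <- function(x, ...) {
  cat(sprintf("pKa fit, %s method, %d points\n", x$method, x$n_points))
  stats::printCoefmat(x$coefficients, ...)
  if (is.finite(x$sigma))
    cat(sprintf("Residual standard error: %.4g\n", x$sigma))
  invisible(x)
}

#' @export
predict.pka_fit <- function(object, newdata = NULL, ...) {
  pH <- if (is.null(newdata)) object$data$pH else
    if (is.data.frame(newdata)) newdata$pH else newdata
  cf <- as.list(object$coefficients)
  f <- ionization_fraction(pH, cf$pKa,
                           slope = if (!is.null(cf$slope)) cf$slope else 1)
  if (object$method %in% c("classical", "tvm")) {
    base <- if (!is.null(cf$mu_neutral)) cf$mu_neutral else 0
    base + (cf$mu_anion - base) * f
  } else {
    cf$beta_acid + (cf$beta_base - cf$beta_acid) * f
  }
}

#' @export
fitted.pka_fit <- function(object, ...) predict(object)

#' @export
residuals.pka_fit <- function(object, ...) object$data$y - fitted(object)

#' @export
plot.pka_fit <- function(x, ...) {
  ylab <- if (x$method == "spectral") "beta" else
    expression(mu[ep] ~ (m^2 ~ V^-1 ~ s^-1))
  graphics::plot(x$data$pH, x$data$y, xlab = "pH", ylab = ylab, ...)
  grid_pH <- seq(min(x$data$pH) - 0.5, max(x$data$pH) + 0.5, length.out = 200)
  graphics::lines(grid_pH, predict(x, grid_pH))
  graphics::abline(v = x$pKa, lty = 2)
  invisible(x)
}

#' @export
simulate.pka_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  sigma <- if (!is.null(object$fit)) summary(object$fit)$sigma else
    stats::sd(residuals(object))
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
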