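#' Van't Hoff analysis of pKa versus temperature
#'
#' Extracts the standard dissociation enthalpy and entropic term from a
#' series of pKa values determined at different temperatures, by ordinary
#' least squares of `ln Ka = -ln(10) * pKa` against `1/T` (T in kelvin):
#' `ln Ka(T) = slope / T + intercept`, with `dH = -R * slope` (reported in
#' kJ mol^-1, R = 8.314 J mol^-1 K^-1).
#'
#' Two entropy-flavoured quantities are returned: `dS_SI = R * intercept`
#' (J mol^-1 K^-1), and `entropic_term`, the dimensionless intercept itself
#' (i.e. dS/R). Published CE thermodynamic tables sometimes print the
#' dimensionless intercept under an entropy heading, so both are exposed and
#' clearly labelled.
#'
#' @param x temperatures (degC), or a formula `pKa ~ temperature`.
#' @param pKa pKa values matching the temperatures (default interface).
#' @param data data.frame for the formula interface.
#' @param ... passed between methods.
#' @return An object of class `"vant_hoff"` with elements `slope` (K),
#'   `intercept`, `dH` (kJ mol^-1), `dS_SI` (J mol^-1 K^-1),
#'   `entropic_term` (dimensionless intercept), their standard errors,
#'   `n`, and the underlying `lm` fit. Supports `print()`, `summary()`,
#'   `coef()`, `predict()` (pKa at new temperatures, degC), `residuals()`
#'   and `plot()`.
#' @examples
#' vant_hoff(c(15, 25, 35, 45, 55), c(5.33, 5.23, 5.12, 5.00, 4.88))
#' @export
vant_hoff <- function(x, ...) UseMethod("vant_hoff")

#' @rdname vant_hoff
#' @export
vant_hoff.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  vant_hoff.default(mf[[2]], mf[[1]], ...)
}

#' @rdname vant_hoff
#' @export
vant_hoff.default <- function(x, pKa, ...) {
  T_C <- x
  if (length(T_C) != length(pKa))
    stop("temperature and pKa vectors must have the same length")
  n_distinct <- length(unique(T_C))
  if (n_distinct < 2)
    stop("Van't Hoff regression needs at least 2 distinct temperatures")
  if (n_distinct == 2 && length(T_C) == 2)
    warning("only two temperatures: slope is a finite difference, ",
            "standard errors are undefined")
  inv_T <- 1 / (T_C + C_TO_K)
  ln_Ka <- -log(10) * pKa
  fit <- stats::lm(ln_Ka ~ inv_T)
  cf <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  slope <- unname(cf["inv_T"])
  intercept <- unname(cf["(Intercept)"])
  structure(list(
    slope = slope, intercept = intercept,
    se_slope = unname(se["inv_T"]), se_intercept = unname(se["(Intercept)"]),
    dH = -R_GAS * slope / 1000, se_dH = R_GAS * unname(se["inv_T"]) / 1000,
    dS_SI = R_GAS * intercept, se_dS_SI = R_GAS * unname(se["(Intercept)"]),
    entropic_term = intercept, se_entropic = unname(se["(Intercept)"]),
    n = length(T_C), data = data.frame(T_C = T_C, pKa = pKa),
    fit = fit, call = match.call()),
    class = "vant_hoff")
}

#' @export
print.vant_hoff <- function(x, ...) {
  cat("Van't Hoff analysis of pKa(T)\n")
  cat(sprintf("  dH  = %.2f kJ/mol (SE %.2f)\n", x$dH, x$se_dH))
  cat(sprintf("  intercept (entropic term, dS/R) = %.2f (SE %.2f)\n",
              x$entropic_term, x$se_entropic))
  cat(sprintf("  dS  = %.2f J/mol/K (SE %.2f)   [n = %d]\n",
              x$dS_SI, x$se_dS_SI, x$n))
  invisible(x)
}

#' @export
coef.vant_hoff <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept,
    dH_kJ_mol = object$dH, dS_J_mol_K = object$dS_SI,
    entropic_term = object$entropic_term)
}

#' @export
summary.vant_hoff <- function(object, ...) summary(object$fit, ...)

#' @export
predict.vant_hoff <- function(object, newdata = NULL, ...) {
  T_C <- if (is.null(newdata)) object$data$T_C else
    if (is.data.frame(newdata)) newdata$T_C else newdata
  ln_Ka <- object$slope / (T_C + C_TO_K) + object$intercept
  -ln_Ka / log(10)
}

#' @export
residuals.vant_hoff <- function(object, ...)
  object$data$pKa - predict(object)

#' @export
plot.vant_hoff <- function(x, ...) {
  inv_T <- 1 / (x$data$T_C + C_TO_K)
  graphics::plot(inv_T, -log(10) * x$data$pKa, xlab = "1/T (1/K)",
                 ylab = expression(ln ~ K[a]), ...)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}
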