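# Canonical internal units are SI (m, V, s, m^2 V^-1 s^-1); user-facing tables
# carry kV and minutes and are converted exactly once, at the I/O boundary.
MIN_TO_S <- 60
KV_TO_V <- 1000
R_GAS <- 8.314  # J mol^-1 K^-1
C_TO_K <- 273.15

#' Capillary geometry
#'
#' Describes the fused-silica (or coated) capillary used for the separation.
#' The inlet section is the part of the capillary outside the thermostated
#' cartridge; it heats more strongly under Joule heating and enters the
#' length-weighted actual-temperature estimate.
#'
#' @param L_tot total capillary length (m).
#' @param L_eff effective (inlet-to-detector) length (m).
#' @param L_inlet non-thermostated inlet length (m).
#' @param inner_diameter internal bore diameter (m).
#'
#' @return An object of class `"capillary_geometry"`.
#' @examples
#' capillary_geometry(0.60, 0.50, 0.04, 50e-6)
#' @export
capillary_geometry <- function(L_tot = 0.60, L_eff = 0.50, L_inlet = 0.04,
                               inner_diameter = 50e-6) {
  stopifnot(is.numeric(L_tot), is.numeric(L_eff), is.numeric(L_inlet),
            is.numeric(inner_diameter))
  if (!(L_inlet > 0 && L_inlet < L_eff && L_eff < L_tot))
    stop("capillary geometry must satisfy 0 < L_inlet < L_eff < L_tot")
  if (inner_diameter <= 0)
    stop("inner_diameter must be positive")
  structure(list(L_tot = L_tot, L_eff = L_eff, L_inlet = L_inlet,
                 inner_diameter = inner_diameter),
            class = "capillary_geometry")
}

#' @export
print.capillary_geometry <- function(x, ...) {
  cat(sprintf(
    "Capillary: %.3g m total, %.3g m to detector, %.3g m inlet, %.0f um i.d.\n",
    x$L_tot, x$L_eff, x$L_inlet, x$inner_diameter * 1e6))
  invisible(x)
}

#' Heat-transfer coefficients for the two capillary sections
#'
#' The electrolyte temperature rise in each section is modelled as
#' proportional to the dissipated power per unit length, `U * I / L_tot`,
#' with one coefficient for the non-thermostated (inlet/outlet) sections and
#' one for the actively cooled core. The coefficients depend on capillary
#' dimensions and the instrument's cooling system and are supplied by the
#' user (typically from a calibration); the defaults give rises of a few
#' degrees C at 30 kV and 50 uA in a 60 cm capillary.
#'
#' @param kappa_noncooled temperature rise per unit linear power density for
#'   the non-thermostated sections (degC m W^-1).
#' @param kappa_cooled same coefficient for the thermostated core section.
#'
#' @return An object of class `"sumet_parameters"`.
#' @export
sumet_parameters <- function(kappa_noncooled = 2.0, kappa_cooled = 0.4) {
  if (!(kappa_noncooled >= kappa_cooled && kappa_cooled >= 0))
    stop("require kappa_noncooled >= kappa_cooled >= 0")
  structure(list(kappa_noncooled = kappa_noncooled,
                 kappa_cooled = kappa_cooled),
            class = "sumet_parameters")
}

#' @export
print.sumet_parameters <- function(x, ...) {
  cat(sprintf("Section heat coefficients (degC m/W): non-cooled %.3g, cooled %.3g\n",
              x$kappa_noncooled, x$kappa_cooled))
  invisible(x)
}
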