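#' Absorbance spectrum at one buffer pH
#'
#' Holds a UV-vis spectrum recorded by the diode-array detector for one
#' buffer pH together with the two analysis wavelengths used by the
#' absorbance-ratio (beta) method. Typical detectors cover 200-600 nm; the
#' two analysis wavelengths must lie within the measured range.
#'
#' @param pH buffer pH.
#' @param wavelengths strictly increasing wavelength grid (nm).
#' @param absorbances absorbance values matching `wavelengths` (AU),
#'   non-negative after baseline handling.
#' @param lambda_1,lambda_2 analysis wavelengths (nm); defaults 270 and 300,
#'   suitable for coumarin acid/base band pairs.
#'
#' @return An object of class `"spectral_record"`.
#' @seealso [beta_parameter()], [read_spectra()]
#' @export
spectral_record <- function(pH, wavelengths, absorbances,
                            lambda_1 = 270, lambda_2 = 300) {
  if (length(wavelengths) != length(absorbances))
    stop("wavelengths and absorbances must have the same length")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(absorbances < 0))
    stop("absorbances must be non-negative")
  rng <- range(wavelengths)
  for (lam in c(lambda_1, lambda_2))
    if (lam < rng[1] || lam > rng[2])
      stop(sprintf("analysis wavelength %.1f nm outside measured range [%.1f, %.1f] nm",
                   lam, rng[1], rng[2]))
  structure(list(pH = pH, wavelengths = wavelengths, absorbances = absorbances,
                 lambda_1 = lambda_1, lambda_2 = lambda_2),
            class = "spectral_record")
}

#' @export
print.spectral_record <- function(x, ...) {
  cat(sprintf("Spectrum at pH %.2f: %d points, %.0f-%.0f nm (analysis %g/%g nm)\n",
              x$pH, length(x$wavelengths), min(x$wavelengths),
              max(x$wavelengths), x$lambda_1, x$lambda_2))
  invisible(x)
}

#' Read spectra from a long-format CSV
#'
#' Expects columns `pH,wavelength_nm,absorbance`. Rows are grouped by pH and
#' sorted by wavelength, so the row order of the input file is immaterial.
#'
#' @param path CSV file path.
#' @inheritParams spectral_record
#' @return A list of [spectral_record] objects ordered by pH.
#' @export
read_spectra <- function(path, lambda_1 = 270, lambda_2 = 300) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pH", "wavelength_nm", "absorbance")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("spectra table is missing column(s): ", paste(missing_cols, collapse = ", "))
  lapply(sort(unique(tab$pH)), function(p) {
    sub <- tab[tab$pH == p, ]
    sub <- sub[order(sub$wavelength_nm), ]
    spectral_record(p, sub$wavelength_nm, sub$absorbance, lambda_1, lambda_2)
  })
}

#' Write spectra to a long-format CSV
#'
#' @param spectra list of [spectral_record] objects.
#' @param path CSV file path.
#' @export
write_spectra <- function(spectra, path) {
  tab <- do.call(rbind, lapply(spectra, function(s)
    data.frame(pH = s$pH, wavelength_nm = s$wavelengths,
               absorbance = s$absorbances)))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Absorbance-ratio ionization observable
#'
#' Computes `beta = A1 / (A1 + A2)` from the absorbances at the record's two
#' analysis wavelengths. Absorbances are linearly interpolated when an
#' analysis wavelength falls between grid points. `beta` varies with pH like
#' the electrophoretic mobility of a monoprotic acid and serves as a
#' mobility-free observable for pKa fitting, e.g. when the host is charged.
#'
#' @param spec a [spectral_record].
#' @return `beta`, a dimensionless value in `[0, 1]`.
#' @export
beta_parameter <- function(spec) {
  stopifnot(inherits(spec, "spectral_record"))
  a1 <- stats::approx(spec$wavelengths, spec$absorbances, xout = spec$lambda_1)$y
  a2 <- stats::approx(spec$wavelengths, spec$absorbances, xout = spec$lambda_2)$y
  if (a1 + a2 <= 0)
    stop("degenerate spectrum: zero total absorbance at the analysis wavelengths")
  a1 / (a1 + a2)
}
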