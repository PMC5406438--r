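#' Host-induced pKa shift
#'
#' Difference between a host-containing and a host-free (reference) result:
#' `delta = host - reference`, with the standard error combined in
#' quadrature. Accepts a pair of [pka_fit] objects (shift in pKa), a pair of
#' [vant_hoff] objects (shifts in dH and the entropic term), or two plain
#' numbers with optional standard errors.
#'
#' @param host result for the host-containing system.
#' @param reference result for the host-free reference system.
#' @param se_host,se_reference standard errors (numeric interface only).
#' @param ... unused.
#' @return An object of class `"pka_shift"`: for pKa pairs, `delta_pKa` and
#'   `se`; for Van't Hoff pairs additionally `delta_dH` (kJ mol^-1) and
#'   `delta_entropic`.
#' @examples
#' pka_shift(5.08, 4.13)  # +0.95
#' @export
pka_shift <- function(host, reference, ...) UseMethod("pka_shift")

#' @rdname pka_shift
#' @export
pka_shift.pka_fit <- function(host, reference, ...) {
  stopifnot(inherits(reference, "pka_fit"))
  if (host$method != reference$method)
    stop(sprintf("method mismatch: host is '%s', reference is '%s'",
                 host$method, reference$method))
  new_pka_shift(host$pKa - reference$pKa,
                sqrt(sum(c(host$se_pKa, reference$se_pKa)^2)))
}

#' @rdname pka_shift
#' @export
pka_shift.vant_hoff <- function(host, reference, ...) {
  stopifnot(inherits(reference, "vant_hoff"))
  out <- new_pka_shift(NA_real_, NA_real_)
  out$delta_dH <- host$dH - reference$dH
  out$se_dH <- sqrt(host$se_dH^2 + reference$se_dH^2)
  out$delta_entropic <- host$entropic_term - reference$entropic_term
  out$se_entropic <- sqrt(host$se_entropic^2 + reference$se_entropic^2)
  # per-temperature pKa shifts where the two fits share temperatures
  shared <- intersect(host$data$T_C, reference$data$T_C)
  if (length(shared)) {
    h <- host$data$pKa[match(shared, host$data$T_C)]
    r <- reference$data$pKa[match(shared, reference$data$T_C)]
    out$by_temperature <- data.frame(T_C = shared, delta_pKa = h - r)
  }
  out
}

#' @rdname pka_shift
#' @export
pka_shift.numeric <- function(host, reference, se_host = NA_real_,
                              se_reference = NA_real_, ...) {
  new_pka_shift(host - reference, sqrt(se_host^2 + se_reference^2))
}

new_pka_shift <- function(delta, se) {
  structure(list(delta_pKa = delta, se = se), class = "pka_shift")
}

#' @export
print.pka_shift <- function(x, ...) {
  if (is.finite(x$delta_pKa[1]))
    cat(sprintf("pKa shift: %+.3f%s\n", x$delta_pKa,
                if (all(is.finite(x$se))) sprintf(" (SE %.3f)", x$se) else ""))
  if (!is.null(x$delta_dH))
    cat(sprintf("dH shift: %+.2f kJ/mol; entropic-term shift: %+.2f\n",
                x$delta_dH, x$delta_entropic))
  if (!is.null(x$by_temperature)) {
    cat("per-temperature pKa shifts:\n")
    print(x$by_temperature, row.names = FALSE)
  }
  invisible(x)
}

#' Compare two-values-method and classical pKa estimates
#'
#' Summarizes the deviation between paired pKa estimates from the fast
#' closed-form screen and the full sigmoid fit.
#'
#' @param pKa_tvm,pKa_classical paired estimates (equal length, >= 1 pair).
#' @return A list with `mean_signed` (mean of classical - tvm),
#'   `mean_abs`, `max_abs`, and the per-pair `table`.
#' @examples
#' compare_methods(c(5.08, 5.03, 4.54, 4.29), c(5.19, 5.18, 4.61, 4.47))
#' @export
compare_methods <- function(pKa_tvm, pKa_classical) {
  if (length(pKa_tvm) == 0)
    stop("need at least one pair of estimates")
  if (length(pKa_tvm) != length(pKa_classical))
    stop("pKa_tvm and pKa_classical must be paired (equal length)")
  d <- pKa_classical - pKa_tvm
  list(mean_signed = mean(d), mean_abs = mean(abs(d)), max_abs = max(abs(d)),
       table = data.frame(pKa_tvm = pKa_tvm, pKa_classical = pKa_classical,
                          delta = d))
}

#' Relative mobility-versus-temperature profiles
#'
#' Normalizes each mobility series by its value at the reference temperature
#' (the lowest temperature by default), so all profiles equal 1 there. The
#' pairwise differences between profiles separate the thermal effects of the
#' overlapped equilibria: the EOF-marker profile reflects viscosity alone;
#' the totally ionized form adds the complexation equilibrium (its profile
#' rises faster when complexation is exothermic); the partially ionized form
#' adds deprotonation (rising faster still when deprotonation is
#' endothermic).
#'
#' @param data data.frame with columns `series`, `temperature` (degC) and
#'   `mobility`.
#' @param T_ref reference temperature; default the minimum shared
#'   temperature. Every series must include it.
#' @return A data.frame with a `rel_mobility` column appended, plus an
#'   attribute `"pairwise"`: a data.frame of profile differences for every
#'   series pair at every temperature.
#' @export
relative_mobility_profile <- function(data, T_ref = NULL) {
  need <- c("series", "temperature", "mobility")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("profile data is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(T_ref)) T_ref <- min(data$temperature)
  parts <- split(data, data$series)
  out <- do.call(rbind, lapply(parts, function(g) {
    i <- which(g$temperature == T_ref)
    if (!length(i))
      stop(sprintf("series '%s' has no measurement at the reference temperature %g degC",
                   g$series[1], T_ref))
    g$rel_mobility <- g$mobility / g$mobility[i[1]]
    g
  }))
  rownames(out) <- NULL
  nm <- names(parts)
  pairs <- if (length(nm) > 1) {
    cmb <- utils::combn(nm, 2)
    do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
      a <- out[out$series == cmb[1, k], ]
      b <- out[out$series == cmb[2, k], ]
      shared <- intersect(a$temperature, b$temperature)
      data.frame(series_a = cmb[1, k], series_b = cmb[2, k],
                 temperature = shared,
                 delta_rel = a$rel_mobility[match(shared, a$temperature)] -
                   b$rel_mobility[match(shared, b$temperature)])
    }))
  } else NULL
  attr(out, "pairwise") <- pairs
  out
}
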