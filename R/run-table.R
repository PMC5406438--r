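#' @name run_table
#' @title CE run tables
#'
#' @description
#' A run table records one row per CE injection: analyte and buffer labels,
#' buffer pH, nominal coolant temperature, voltage program (nominal voltage
#' and ramp time), migration times of the analyte and of the neutral EOF
#' marker, the plateau current, and a replicate index. Times are in minutes
#' and voltage in kV, as instrument software reports them; all mobility
#' computations convert to SI internally.
#'
#' `read_run_table()` and `write_run_table()` round-trip the CSV format with
#' header `analyte_id,buffer_id,pH,T_coolant_C,U_nom_kV,t_ramp_min,t_tot_min,
#' t_eof_min,current_uA,replicate`. `validate_run_table()` enforces the row
#' invariants (positive times, non-zero voltage, ramp shorter than either
#' migration time) and reports offending rows by index.
NULL

RUN_TABLE_COLUMNS <- c("analyte_id", "buffer_id", "pH", "T_coolant_C",
                       "U_nom_kV", "t_ramp_min", "t_tot_min", "t_eof_min",
                       "current_uA", "replicate")

#' Validate a CE run table
#'
#' @param runs data.frame with the columns listed in [run_table].
#' @return `runs`, invisibly, with columns in canonical order.
#' @rdname run_table
#' @export
validate_run_table <- function(runs) {
  missing_cols <- setdiff(RUN_TABLE_COLUMNS, names(runs))
  if (length(missing_cols))
    stop("run table is missing column(s): ", paste(missing_cols, collapse = ", "))
  runs <- runs[RUN_TABLE_COLUMNS]
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx))
      stop(sprintf("invalid run record(s) at row(s) %s: %s",
                   paste(idx, collapse = ", "), what))
  }
  bad(!(runs$t_tot_min > 0), "t_tot_min must be > 0")
  bad(!(runs$t_eof_min > 0), "t_eof_min must be > 0")
  bad(runs$U_nom_kV == 0, "U_nom_kV must be non-zero")
  bad(runs$t_ramp_min < 0, "t_ramp_min must be >= 0")
  bad(runs$t_ramp_min >= pmin(runs$t_tot_min, runs$t_eof_min),
      "t_ramp_min must be smaller than both migration times")
  invisible(runs)
}

#' @param path CSV file path.
#' @rdname run_table
#' @export
read_run_table <- function(path) {
  runs <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_run_table(runs)
  runs[RUN_TABLE_COLUMNS]
}

#' @rdname run_table
#' @export
write_run_table <- function(runs, path) {
  runs <- validate_run_table(runs)
  out <- runs
  # 17 significant digits: numeric fields survive the round trip bit-exactly
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x)
    ifelse(is.na(x), NA, formatC(x, format = "g", digits = 17)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
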