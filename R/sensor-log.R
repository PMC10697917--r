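#' Read or write a sensor log CSV
#'
#' The sensor log dialect is a plain UTF-8 CSV with header
#' `t,s1,s2,s3,s4[,gamma_deg]`: time in seconds at a nominal 100 Hz, four raw
#' channel signals, and (for intraoperative trials) the hip flexion angle in
#' degrees recorded alongside.
#'
#' @param path File path.
#' @param log A data frame with the columns above.
#' @param check_rate Verify that the sampling interval is consistent with
#'   100 Hz (within 1 %).
#' @return `read_sensor_log()` returns a tibble; `write_sensor_log()` returns
#'   `path` invisibly.
#' @export
read_sensor_log <- function(path, check_rate = TRUE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("t", paste0("s", 1:4))
  if (!all(need %in% names(df))) {
    abort(sprintf("Sensor log CSV must have columns %s.",
                  paste(need, collapse = ", ")))
  }
  if (check_rate && nrow(df) > 1L) check_sampling_rate(df$t)
  df
}

#' @rdname read_sensor_log
#' @export
write_sensor_log <- function(log, path) {
  need <- c("t", paste0("s", 1:4))
  stopifnot(all(need %in% names(log)))
  keep <- intersect(c(need, "gamma_deg"), names(log))
  readr::write_csv(dplyr::select(log, dplyr::all_of(keep)), path, progress = FALSE)
  invisible(path)
}

check_sampling_rate <- function(t, nominal_hz = 100, tol = 0.01) {
  dt <- diff(t)
  if (any(dt <= 0) || any(abs(dt - 1 / nominal_hz) > tol / nominal_hz)) {
    abort(sprintf("Sampling interval inconsistent with %g Hz (within %g%%).",
                  nominal_hz, 100 * tol))
  }
  invisible(t)
}

#' Assemble a trial recording
#'
#' Binds a sensor log and flexion-angle trace to the patient's implant
#' geometry and identifier. The flexion trace must be sample-aligned with the
#' channel signals.
#'
#' @param log A data frame with columns `t`, `s1`..`s4` and `gamma_deg` (or
#'   pass `gamma_deg` separately).
#' @param geometry A [patient_geometry()].
#' @param patient_id Identifier carried into summaries.
#' @param gamma_deg Optional flexion-angle vector overriding `log$gamma_deg`.
#' @return A `trial_recording`: the log tibble with attributes `geometry` and
#'   `patient_id`.
#' @export
trial_recording <- function(log, geometry, patient_id = "patient",
                            gamma_deg = NULL) {
  stopifnot(inherits(geometry, "patient_geometry"))
  log <- as_tibble(log)
  if (!is.null(gamma_deg)) log$gamma_deg <- gamma_deg
  need <- c("t", paste0("s", 1:4), "gamma_deg")
  if (!all(need %in% names(log))) {
    abort(sprintf("A trial recording needs columns %s.", paste(need, collapse = ", ")))
  }
  if (any(!is.finite(log$gamma_deg)) ||
      any(log$gamma_deg < -10) || any(log$gamma_deg > 120)) {
    abort("Flexion angles must be finite and within [-10, 120] degrees.")
  }
  structure(log, geometry = geometry, patient_id = patient_id,
            class = c("trial_recording", class(log)))
}
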