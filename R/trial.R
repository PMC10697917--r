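#' Segment a flexion trace into passive range-of-motion cycles
#'
#' The intraoperative protocol takes the hip from 0 degrees extension to 90
#' degrees flexion three times. This finds the rising limb of each cycle:
#' after smoothing the flexion trace with a centred moving average (0.25 s at
#' the nominal sampling rate, enough to suppress sensor noise without
#' distorting the slow passive motion), it returns every maximal
#' monotone-increasing sweep that starts below `lo_deg` and ends above
#' `hi_deg`.
#'
#' @param gamma_deg Flexion angle trace in degrees.
#' @param fs_hz Sampling rate (Hz), used to size the smoothing window.
#' @param smooth_s Smoothing window in seconds.
#' @param lo_deg,hi_deg A sweep qualifies as a cycle when it rises from below
#'   `lo_deg` to above `hi_deg`.
#' @return A tibble with one row per cycle: `cycle`, `start`, `end` (sample
#'   indices, inclusive). When no complete sweep exists the tibble is empty
#'   and carries a `diagnostic` attribute saying so.
#' @examples
#' g <- c(seq(0, 90, by = 1), seq(89, 1, by = -1))
#' segment_cycles(g, fs_hz = 100)
#' @export
segment_cycles <- function(gamma_deg, fs_hz = 100, smooth_s = 0.25,
                           lo_deg = 5, hi_deg = 85) {
  stopifnot(is.numeric(gamma_deg), length(gamma_deg) >= 2L)
  g <- moving_average(gamma_deg, max(1L, round(smooth_s * fs_hz)))
  inc <- diff(g) > 0
  r <- rle(inc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- purrr::map_dfr(which(r$values), function(k) {
    i0 <- starts[k]; i1 <- ends[k] + 1L   # run of diffs -> samples i0..i1
    if (g[i0] < lo_deg && g[i1] > hi_deg) tibble(start = i0, end = i1) else NULL
  })
  if (nrow(out) == 0L) {
    out <- tibble(cycle = integer(), start = integer(), end = integer())
    attr(out, "diagnostic") <-
      sprintf("No complete sweep from below %g to above %g degrees found.",
              lo_deg, hi_deg)
    return(out)
  }
  dplyr::mutate(out, cycle = dplyr::row_number(), .before = 1L)
}

moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  k <- min(k, length(x))
  pad <- c(rep(x[1L], k), x, rep(x[length(x)], k))
  cs <- cumsum(pad)
  half_lo <- k %/% 2L
  half_hi <- k - half_lo - 1L
  idx <- seq_along(x) + k
  (cs[idx + half_hi] - cs[idx - half_lo - 1L]) / k
}

#' Summarise one passive flexion cycle
#'
#' Extracts the four trial metrics from the resultant-force and flexion
#' traces of a single cycle: the maximum force, anchored to the most extended
#' posture (the sample of minimum flexion, where soft-tissue tension is
#' greatest); the global minimum force and the flexion angle at which it
#' occurs (ties broken by the earliest sample); and the force at 90 degrees
#' flexion, linearly interpolated in flexion angle (or read at the last
#' sample when the sweep tops out between 85 and 90 degrees).
#'
#' @param resultant_N Resultant force trace (Newtons) over the cycle.
#' @param gamma_deg Flexion trace (degrees), same length.
#' @return A one-row tibble: `max_force_N`, `min_force_N`,
#'   `gamma_at_min_deg`, `force_at_90_N`.
#' @examples
#' g <- 0:90
#' r <- (g - 40)^2 / 10 + 100
#' summarize_cycle(r, g)   # min 100 N at 40 deg, 260 N extended, 350 N at 90
#' @export
summarize_cycle <- function(resultant_N, gamma_deg) {
  stopifnot(is.numeric(resultant_N), is.numeric(gamma_deg),
            length(resultant_N) == length(gamma_deg))
  if (length(resultant_N) < 10L) {
    abort("Cycle too short to summarise (fewer than 10 samples).")
  }
  if (any(!is.finite(resultant_N)) || any(!is.finite(gamma_deg))) {
    abort("Cycle contains non-finite samples.")
  }
  i_ext <- which.min(gamma_deg)              # most extended posture
  i_min <- which.min(resultant_N)            # earliest on ties
  g_max <- max(gamma_deg)
  f90 <- if (g_max >= 90) {
    approx(gamma_deg, resultant_N, xout = 90, ties = mean)$y
  } else if (g_max >= 85) {
    resultant_N[which.max(gamma_deg)]
  } else {
    abort("Cycle does not reach 85 degrees flexion.")
  }
  tibble(
    max_force_N = resultant_N[i_ext],
    min_force_N = resultant_N[i_min],
    gamma_at_min_deg = gamma_deg[i_min],
    force_at_90_N = f90
  )
}

#' Coefficient of variation in percent
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation. Used both
#' within patients (across repeated cycles) and between patients (across
#' per-patient means).
#'
#' @param values Numeric vector.
#' @return The COV in percent; `NA` (a missing-value flag) when fewer than
#'   two finite values are available or the mean is zero.
#' @examples
#' cov_pct(c(116.9, 135.0, 134.5, 93.0))   # 16.5
#' @export
cov_pct <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2L) return(NA_real_)
  m <- mean(v)
  if (m == 0) return(NA_real_)
  100 * stats::sd(v) / m
}

trial_metrics <- c("max_force_N", "min_force_N", "gamma_at_min_deg", "force_at_90_N")

#' Run the full trial pipeline on one recording
#'
#' Reconstructs the head-frame force at every sample, transforms it into the
#' pelvic frame with the per-sample flexion angle, forms the reported
#' component triple and resultant, segments the flexion trace into cycles,
#' summarises each cycle, and aggregates per-metric mean, range and
#' intrasubject COV. Cycles whose summary fails (too short, corrupted
#' samples) are flagged and excluded from the aggregates, never silently
#' dropped.
#'
#' @param recording A [trial_recording()].
#' @param cal A [calibration_model()].
#' @return A `patient_summary`: list with `patient_id`, `cycles` (per-cycle
#'   metrics with `ok`/`note` flags), `metrics` (per-metric mean, range and
#'   `cov_pct`, with the COV flagged missing when fewer than two valid
#'   cycles exist), `n_valid_cycles`, and the processed sample table.
#' @export
run_trial <- function(recording, cal) {
  stopifnot(inherits(recording, "trial_recording"),
            inherits(cal, "calibration_model"))
  geometry <- attr(recording, "geometry")
  df <- as_tibble(recording)
  df <- reconstruct_forces(df, cal)
  df <- add_reported_components(df, geometry)
  seg <- segment_cycles(df$gamma_deg)
  if (nrow(seg) == 0L) {
    abort(paste("Cycle segmentation failed:",
                attr(seg, "diagnostic") %||% "no cycles found."))
  }
  cycles <- purrr::pmap_dfr(seg, function(cycle, start, end) {
    idx <- start:end
    res <- tryCatch(
      dplyr::mutate(summarize_cycle(df$resultant_N[idx], df$gamma_deg[idx]),
                    cycle = cycle, ok = TRUE, note = NA_character_,
                    .before = 1L),
      error = function(e) tibble(
        cycle = cycle, ok = FALSE, note = conditionMessage(e),
        max_force_N = NA_real_, min_force_N = NA_real_,
        gamma_at_min_deg = NA_real_, force_at_90_N = NA_real_)
    )
    res
  })
  patient_summary(cycles, patient_id = attr(recording, "patient_id"),
                  geometry = geometry, samples = df)
}

#' Build a patient summary from per-cycle metrics
#'
#' @param cycles A tibble of per-cycle metrics (see [run_trial()]); an `ok`
#'   column marks valid cycles (assumed all valid when absent).
#' @param patient_id Identifier.
#' @param geometry Optional [patient_geometry()].
#' @param samples Optional processed sample table, kept for plotting.
#' @return A `patient_summary` object.
#' @export
patient_summary <- function(cycles, patient_id = "patient", geometry = NULL,
                            samples = NULL) {
  cycles <- as_tibble(cycles)
  stopifnot(all(trial_metrics %in% names(cycles)))
  if (!"ok" %in% names(cycles)) cycles$ok <- TRUE
  if (!"cycle" %in% names(cycles)) cycles$cycle <- seq_len(nrow(cycles))
  valid <- dplyr::filter(cycles, .data$ok)
  metrics <- purrr::map_dfr(trial_metrics, function(m) {
    v <- valid[[m]]
    tibble(metric = m,
           mean = if (length(v)) mean(v) else NA_real_,
           range_lo = if (length(v)) min(v) else NA_real_,
           range_hi = if (length(v)) max(v) else NA_real_,
           cov_pct = cov_pct(v),         # NA flags < 2 valid cycles
           n_cycles = length(v))
  })
  structure(list(patient_id = patient_id, cycles = cycles, metrics = metrics,
                 n_valid_cycles = nrow(valid), geometry = geometry,
                 samples = samples),
            class = "patient_summary")
}

#' @export
print.patient_summary <- function(x, ...) {
  cat(sprintf("<patient_summary> %s: %d/%d valid cycles\n",
              x$patient_id, x$n_valid_cycles, nrow(x$cycles)))
  print(x$metrics)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.patient_summary <- function(x, ...) x$metrics

#' @exportS3Method generics::glance
glance.patient_summary <- function(x, ...) {
  tibble(patient_id = x$patient_id, n_cycles = nrow(x$cycles),
         n_valid_cycles = x$n_valid_cycles,
         mean_max_force_N = x$metrics$mean[x$metrics$metric == "max_force_N"],
         mean_min_force_N = x$metrics$mean[x$metrics$metric == "min_force_N"])
}

#' Read or write a patient summary as JSON
#'
#' @param summary A `patient_summary` (sample table is not serialised).
#' @param path File path.
#' @return `read_patient_summary_json()` returns a `patient_summary`;
#'   the writer returns `path` invisibly.
#' @export
write_patient_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "patient_summary"))
  jsonlite::write_json(
    list(patient_id = summary$patient_id,
         cycles = summary$cycles,
         metrics = summary$metrics,
         n_valid_cycles = summary$n_valid_cycles,
         geometry = if (!is.null(summary$geometry)) unclass(summary$geometry)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_patient_summary_json
#' @export
read_patient_summary_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- if (!is.null(x$geometry)) {
    patient_geometry(x$geometry$delta_deg, x$geometry$epsilon_deg,
                     x$geometry$chi_deg, side = x$geometry$side)
  }
  patient_summary(as_tibble(x$cycles), patient_id = x$patient_id,
                  geometry = geom)
}
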