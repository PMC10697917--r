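#' Cohort-level summary statistics
#'
#' Aggregates per-patient trial summaries the way the study reports them:
#' for each metric the cohort mean is the mean of patient means, the
#' intersubject COV is [cov_pct()] over the patient means, and the mean
#' intrasubject COV is the mean of per-patient COVs, excluding patients whose
#' COV is flagged missing (fewer than two valid cycles).
#'
#' @param patients Either a list of `patient_summary` objects or a data frame
#'   of per-patient means with a `patient_id` column and one column per
#'   metric (`max_force_N`, `min_force_N`, `gamma_at_min_deg`,
#'   `force_at_90_N`; any subset is accepted).
#' @return A `cohort_stats` tibble: one row per metric with `cohort_mean`,
#'   `mean_intrasubject_cov_pct`, `intersubject_cov_pct`, `n_patients`.
#' @examples
#' means <- tibble::tibble(
#'   patient_id = paste0("P", 1:4),
#'   max_force_N = c(312.0, 384.7, 791.2, 186.9),
#'   gamma_at_min_deg = c(30.0, 39.4, 46.2, 15.7)
#' )
#' cohort_stats(means)
#' @export
cohort_stats <- function(patients) {
  if (is.data.frame(patients)) {
    means <- as_tibble(patients)
    metrics <- intersect(trial_metrics, names(means))
    if (length(metrics) == 0L) {
      abort("No trial metric columns found in the per-patient means table.")
    }
    intra <- NULL
  } else if (is.list(patients) && all(purrr::map_lgl(patients, inherits,
                                                     "patient_summary"))) {
    means <- purrr::map_dfr(patients, function(p) {
      wide <- tidyr::pivot_wider(p$metrics[, c("metric", "mean")],
                                 names_from = "metric", values_from = "mean")
      dplyr::mutate(wide, patient_id = p$patient_id, .before = 1L)
    })
    intra <- purrr::map_dfr(patients, function(p) {
      wide <- tidyr::pivot_wider(p$metrics[, c("metric", "cov_pct")],
                                 names_from = "metric", values_from = "cov_pct")
      dplyr::mutate(wide, patient_id = p$patient_id, .before = 1L)
    })
    metrics <- trial_metrics
  } else {
    abort("`patients` must be a list of patient_summary objects or a data frame of per-patient means.")
  }
  if (nrow(means) < 2L) abort("Cohort statistics need at least two patients.")
  out <- purrr::map_dfr(metrics, function(m) {
    v <- means[[m]]
    tibble(metric = m,
           cohort_mean = mean(v, na.rm = TRUE),
           mean_intrasubject_cov_pct = if (is.null(intra)) NA_real_ else
             mean(intra[[m]], na.rm = TRUE),
           intersubject_cov_pct = cov_pct(v),
           n_patients = sum(is.finite(v)))
  })
  structure(out, class = c("cohort_stats", class(out)))
}

#' Write the cohort table as CSV
#'
#' Produces a tidy long table mirroring the study's summary layout: one row
#' per metric and patient carrying the per-patient mean, range and
#' intrasubject COV, followed per metric by cohort rows (`COHORT_MEAN`,
#' `MEAN_INTRASUBJECT_COV`, `INTERSUBJECT_COV`).
#'
#' @param patients A list of `patient_summary` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(patients, path) {
  stopifnot(is.list(patients),
            all(purrr::map_lgl(patients, inherits, "patient_summary")))
  per_patient <- purrr::map_dfr(patients, function(p) {
    dplyr::mutate(p$metrics, patient_id = p$patient_id, .before = 1L)
  })
  cs <- cohort_stats(patients)
  cohort_rows <- purrr::map_dfr(seq_len(nrow(cs)), function(i) {
    tibble(patient_id = c("COHORT_MEAN", "MEAN_INTRASUBJECT_COV",
                          "INTERSUBJECT_COV"),
           metric = cs$metric[i],
           mean = c(cs$cohort_mean[i], NA, NA),
           range_lo = NA_real_, range_hi = NA_real_,
           cov_pct = c(NA, cs$mean_intrasubject_cov_pct[i],
                       cs$intersubject_cov_pct[i]),
           n_cycles = NA_integer_)
  })
  readr::write_csv(dplyr::bind_rows(per_patient, cohort_rows), path,
                   progress = FALSE)
  invisible(path)
}
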