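#' Plot a model sweep
#'
#' Reported force components and resultant of the passive model prediction
#' against flexion angle.
#'
#' @param object A `hip_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.hip_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("gamma_deg", "posterior_N", "inferior_N",
                          "medial_N", "resultant_N")],
    -"gamma_deg", names_to = "component", values_to = "force_N")
  ggplot2::ggplot(long, ggplot2::aes(.data$gamma_deg, .data$force_N,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Hip flexion (deg)", y = "Force (N)",
                  colour = NULL,
                  title = "Passive model hip joint reaction") +
    ggplot2::theme_minimal()
}

#' Plot a processed trial
#'
#' Resultant joint force against flexion angle for every segmented cycle of
#' a patient's trial.
#'
#' @param object A `patient_summary` that retains its sample table.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.patient_summary <- function(object, ...) {
  df <- object$samples
  if (is.null(df)) abort("This patient_summary does not retain its sample table.")
  seg <- segment_cycles(df$gamma_deg)
  cyc <- dplyr::bind_rows(purrr::pmap(seg, function(cycle, start, end) {
    dplyr::mutate(df[start:end, c("gamma_deg", "resultant_N")],
                  cycle = factor(cycle))
  }))
  ggplot2::ggplot(cyc, ggplot2::aes(.data$gamma_deg, .data$resultant_N,
                                    colour = .data$cycle)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "Hip flexion (deg)", y = "Resultant force (N)",
                  colour = "Cycle",
                  title = paste("Soft-tissue tension:", object$patient_id)) +
    ggplot2::theme_minimal()
}

#' Plot raw sensor channels of a recording
#'
#' @param object A `trial_recording`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.trial_recording <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object)[, c("t", paste0("s", 1:4))],
                              -"t", names_to = "channel",
                              values_to = "signal")
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$signal,
                                     colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Raw signal (units)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
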