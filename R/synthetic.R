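#' Specification of a virtual patient for the synthetic generator
#'
#' The generator emulates the measured behaviour of passive soft-tissue
#' tension: a U-shaped resultant over the flexion sweep (high in extension,
#' interior minimum in mid-flexion, rising again to 90 degrees), a
#' predominantly superior force direction in extension rotating smoothly
#' toward posterior at deep flexion, and a small, nearly constant
#' mediolateral component. The four anchors parameterise the resultant; the
#' crossover angles parameterise the direction swing.
#'
#' Defaults reproduce the mean per-cycle metrics of the modelled reference
#' patient (patient 4 of the intraoperative series; see
#' [reference_cohort()]).
#'
#' @param f_ext_N Resultant at full extension (gamma = 0), Newtons.
#' @param f_min_N Minimum resultant over the sweep, Newtons. Must not exceed
#'   `f_ext_N` or `f_90_N`.
#' @param gamma_min_deg Flexion angle of the minimum, degrees, in (0, 90).
#' @param f_90_N Resultant at 90 degrees flexion, Newtons.
#' @param gamma_ap_deg Anterior-to-posterior crossover: flexion angle where
#'   the posterior component crosses zero. Default 0 (posterior component
#'   non-negative throughout).
#' @param gamma_si_deg Superior-to-inferior crossover: flexion angle where
#'   the supero-inferior component crosses zero. Default 90.
#' @param medial_frac Constant mediolateral component as a fraction of
#'   `f_min_N`.
#' @param geometry A [patient_geometry()].
#' @param noise A [noise_spec()] applied to the sensor channels.
#' @param n_cycles Number of flexion cycles (default 3, the trial protocol).
#' @param seed Integer seed making the recording deterministic.
#' @return An object of class `virtual_patient_spec`.
#' @export
virtual_patient_spec <- function(f_ext_N = 186.9, f_min_N = 93.0,
                                 gamma_min_deg = 15.7, f_90_N = 155.1,
                                 gamma_ap_deg = 0, gamma_si_deg = 90,
                                 medial_frac = 0.25,
                                 geometry = patient_geometry(),
                                 noise = noise_spec(), n_cycles = 3,
                                 seed = 1) {
  stopifnot(inherits(geometry, "patient_geometry"), inherits(noise, "noise_spec"))
  if (!all(is.finite(c(f_ext_N, f_min_N, gamma_min_deg, f_90_N))) ||
      f_ext_N <= 0 || f_min_N <= 0 || f_90_N <= 0) {
    abort("Force anchors must be positive and finite.")
  }
  if (f_min_N > min(f_ext_N, f_90_N)) {
    abort("`f_min_N` must not exceed `f_ext_N` or `f_90_N`.")
  }
  if (gamma_min_deg <= 0 || gamma_min_deg >= 90) {
    abort("`gamma_min_deg` must lie strictly inside (0, 90).")
  }
  if (gamma_si_deg <= gamma_ap_deg) {
    abort("`gamma_si_deg` must exceed `gamma_ap_deg`.")
  }
  structure(list(f_ext_N = f_ext_N, f_min_N = f_min_N,
                 gamma_min_deg = gamma_min_deg, f_90_N = f_90_N,
                 gamma_ap_deg = gamma_ap_deg, gamma_si_deg = gamma_si_deg,
                 medial_frac = medial_frac, geometry = geometry,
                 noise = noise, n_cycles = n_cycles, seed = seed),
            class = "virtual_patient_spec")
}

# Shape-preserving U: two monotone cubic Hermite (smoothstep) pieces through
# (0, f_ext), (gamma_min, f_min), (90, f_90) with zero slope at the minimum
# and the outer ends, so the resultant never undershoots f_min.
u_resultant <- function(gamma_deg, spec) {
  h <- function(u) u^2 * (3 - 2 * u)
  gm <- spec$gamma_min_deg
  ifelse(gamma_deg <= gm,
         spec$f_min_N + (spec$f_ext_N - spec$f_min_N) * h((gm - gamma_deg) / gm),
         spec$f_min_N + (spec$f_90_N - spec$f_min_N) * h((gamma_deg - gm) / (90 - gm)))
}

#' Ground-truth pelvic-frame force trajectory
#'
#' Evaluates the virtual patient's force trajectory on a flexion grid. The
#' resultant interpolates the three anchors with shape-preserving monotone
#' cubics; the mediolateral component is constant
#' (`medial_frac * f_min_N`); the in-plane direction rotates linearly in the
#' crossover parameterisation from superior at extension toward posterior at
#' deep flexion. Components recombine to the specified resultant exactly.
#'
#' @param spec A [virtual_patient_spec()].
#' @param gamma_deg Flexion grid in degrees, within `[0, 90]`.
#' @return A tibble with `gamma_deg`, pelvic components `fx_pelvis`,
#'   `fy_pelvis`, `fz_pelvis`, and the reported triple `posterior_N`,
#'   `inferior_N`, `medial_N` with `resultant_N`.
#' @export
truth_trajectory <- function(spec, gamma_deg = seq(0, 90, by = 1)) {
  stopifnot(inherits(spec, "virtual_patient_spec"))
  if (any(gamma_deg < 0) || any(gamma_deg > 90)) {
    abort("`gamma_deg` grid must lie within [0, 90].")
  }
  R <- u_resultant(gamma_deg, spec)
  m0 <- spec$medial_frac * spec$f_min_N
  if (m0 >= min(R)) abort("Mediolateral component exceeds the minimum resultant.")
  P <- sqrt(R^2 - m0^2)
  beta <- deg2rad(90 * (gamma_deg - spec$gamma_ap_deg) /
                    (spec$gamma_si_deg - spec$gamma_ap_deg))
  posterior <- P * sin(beta)
  inferior <- -P * cos(beta)
  med_sign <- if (spec$geometry$side == "RIGHT") -1 else 1
  tibble(
    gamma_deg = gamma_deg,
    fx_pelvis = -posterior,
    fy_pelvis = med_sign * m0,
    fz_pelvis = inferior,
    posterior_N = posterior,
    inferior_N = inferior,
    medial_N = m0,
    resultant_N = R
  )
}

# Triangular flexion profile: 0 -> 90 -> 0 at 100 Hz, `half_sweep_s` per limb.
triangular_gamma <- function(n_cycles, half_sweep_s = 15, fs_hz = 100) {
  up <- seq(0, 90, length.out = half_sweep_s * fs_hz + 1L)
  cyc <- c(up, rev(up)[-1L])
  g <- cyc
  for (i in seq_len(n_cycles - 1L)) g <- c(g, cyc[-1L])
  g
}

#' Generate a synthetic trial recording with ground truth
#'
#' Builds the flexion profile (triangular 0-90-0 sweeps, 15 s per half-sweep
#' at 100 Hz -- slow passive motion), evaluates the ground-truth pelvic
#' force at every sample, maps it into the head frame by the inverse of the
#' reporting transformation chain, projects it onto the four sensor channels
#' with the spec's noise model, and returns the raw recording together with
#' the ground-truth cycle metrics. Deterministic given `spec$seed`.
#'
#' @param spec A [virtual_patient_spec()].
#' @param cal A [calibration_model()] used for the forward projection.
#' @param patient_id Identifier stamped on the recording.
#' @param half_sweep_s Seconds per half-sweep of the triangular profile.
#' @return A list: `recording` (a [trial_recording()]), `truth` (one-row
#'   tibble of the four cycle metrics implied by the spec), `trajectory`
#'   (per-sample ground truth), and `spec`.
#' @export
generate_recording <- function(spec, cal = calibration_model(),
                               patient_id = "virtual", half_sweep_s = 15) {
  stopifnot(inherits(spec, "virtual_patient_spec"),
            inherits(cal, "calibration_model"))
  g <- triangular_gamma(spec$n_cycles, half_sweep_s)
  traj <- truth_trajectory(spec, g)
  fmat <- t(as.matrix(traj[, c("fx_pelvis", "fy_pelvis", "fz_pelvis")]))
  fhead <- head_from_pelvis_mat(fmat, g, spec$geometry)
  smat <- local_seed(spec$seed, project_forces_mat(fhead, cal, spec$noise))
  n <- length(g)
  log <- tibble(t = (seq_len(n) - 1L) / 100,
                s1 = smat[, 1L], s2 = smat[, 2L], s3 = smat[, 3L],
                s4 = smat[, 4L], gamma_deg = g)
  truth <- tibble(max_force_N = spec$f_ext_N, min_force_N = spec$f_min_N,
                  gamma_at_min_deg = spec$gamma_min_deg,
                  force_at_90_N = spec$f_90_N)
  list(recording = trial_recording(log, spec$geometry, patient_id = patient_id),
       truth = truth, trajectory = traj, spec = spec)
}

#' Reference per-patient trial metrics
#'
#' Mean per-cycle metrics of the four patients measured intraoperatively in
#' the series the instrument was validated on. Used as anchors for the
#' synthetic cohort generator and for cohort-statistics regression checks.
#'
#' @return A tibble with `patient_id` and the four trial metrics.
#' @export
reference_cohort <- function() {
  tibble(
    patient_id = paste0("P", 1:4),
    max_force_N = c(312.0, 384.7, 791.2, 186.9),
    min_force_N = c(116.9, 135.0, 134.5, 93.0),
    gamma_at_min_deg = c(30.0, 39.4, 46.2, 15.7),
    force_at_90_N = c(279.8, 174.9, 222.5, 155.1)
  )
}

#' Specification of a synthetic cohort
#'
#' Per-patient force magnitudes are drawn log-normally: joint forces are
#' positive and the measured between-patient spread is large and
#' right-skewed. Each metric's log-normal is parameterised by its cohort
#' mean and coefficient of variation; with `cv = 0` every patient receives
#' the mean (degenerate distribution).
#'
#' Default means and CVs follow the measured four-patient cohort
#' ([reference_cohort()] and its intersubject COVs).
#'
#' @param n_patients Number of patients (at least 2).
#' @param means Named numeric: cohort means for `f_ext_N`, `f_min_N`,
#'   `gamma_min_deg`, `f_90_N`.
#' @param cvs Named numeric: coefficients of variation (fractions, not
#'   percent) for the same four quantities.
#' @param geometry,noise,n_cycles Passed to each [virtual_patient_spec()].
#' @param seed Integer seed for all draws.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 4,
                        means = c(f_ext_N = 418.7, f_min_N = 120.0,
                                  gamma_min_deg = 32.8, f_90_N = 204.5),
                        cvs = c(f_ext_N = 0.583, f_min_N = 0.165,
                                gamma_min_deg = 0.402, f_90_N = 0.242),
                        geometry = patient_geometry(), noise = noise_spec(),
                        n_cycles = 3, seed = 1) {
  stopifnot(n_patients >= 2, all(cvs >= 0), all(means > 0))
  need <- c("f_ext_N", "f_min_N", "gamma_min_deg", "f_90_N")
  if (!all(need %in% names(means)) || !all(need %in% names(cvs))) {
    abort(sprintf("`means` and `cvs` must name %s.", paste(need, collapse = ", ")))
  }
  structure(list(n_patients = as.integer(n_patients), means = means,
                 cvs = cvs, geometry = geometry, noise = noise,
                 n_cycles = n_cycles, seed = seed),
            class = "cohort_spec")
}

rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic multi-patient cohort
#'
#' Draws one [virtual_patient_spec()] per patient from the cohort
#' distributions (redrawing the rare combinations that violate the U-shape
#' constraints), generates each patient's recording, and returns the
#' recordings with a truth table of per-patient metrics.
#'
#' @param spec A [cohort_spec()].
#' @param cal A [calibration_model()] for the forward projection.
#' @return A list: `patients` (per patient, the [generate_recording()]
#'   output) and `truth` (tibble of per-patient ground-truth metrics).
#' @export
generate_cohort <- function(spec, cal = calibration_model()) {
  stopifnot(inherits(spec, "cohort_spec"))
  draws <- local_seed(spec$seed, {
    purrr::map(seq_len(spec$n_patients), function(i) {
      for (attempt in 1:100) {
        v <- purrr::imap_dbl(spec$means[c("f_ext_N", "f_min_N",
                                          "gamma_min_deg", "f_90_N")],
                             function(m, nm) rlnorm_mean_cv(1L, m, spec$cvs[[nm]]))
        ok <- v[["f_min_N"]] <= min(v[["f_ext_N"]], v[["f_90_N"]]) &&
          v[["gamma_min_deg"]] > 0 && v[["gamma_min_deg"]] < 90
        if (ok) return(v)
      }
      abort("Could not draw a valid patient spec in 100 attempts.")
    })
  })
  patients <- purrr::imap(draws, function(v, i) {
    ps <- virtual_patient_spec(
      f_ext_N = v[["f_ext_N"]], f_min_N = v[["f_min_N"]],
      gamma_min_deg = v[["gamma_min_deg"]], f_90_N = v[["f_90_N"]],
      geometry = spec$geometry, noise = spec$noise,
      n_cycles = spec$n_cycles,
      seed = (spec$seed + 7919L * i) %% .Machine$integer.max)
    generate_recording(ps, cal, patient_id = sprintf("SIM%02d", i))
  })
  truth <- purrr::imap_dfr(patients, function(p, i) {
    dplyr::mutate(p$truth, patient_id = sprintf("SIM%02d", i), .before = 1L)
  })
  list(patients = patients, truth = truth)
}
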