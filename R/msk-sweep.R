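#' Static-equilibrium hip joint reaction at one pose
#'
#' At a given joint configuration every hip-spanning muscle contributes its
#' passive force along the path segment adjacent to its pelvis-side
#' attachment (via points deviate the line of action), and gravity
#' contributes the weight of the hanging limb (thigh + shank + foot) acting
#' posteriorly on the supine patient. The joint reaction -- the force the
#' femoral head exerts on the pelvis -- is equal and opposite to the sum of
#' the muscle pulls on the pelvis and the transmitted limb weight; inertial
#' terms are excluded because passive trial motion is slow.
#'
#' @param model A [muscle_model()].
#' @param state A [joint_state()].
#' @param gravity Include the gravity contribution? (`FALSE` isolates the
#'   muscle term.)
#' @return A [force_vector()] in the pelvic frame, with attributes
#'   `muscle_forces` (per-muscle tibble: path length, normalised fibre
#'   length, force magnitude and direction) and `balance` (list with
#'   `muscle_on_pelvis`, `gravity_transmitted` and `residual`, where
#'   `reaction + sum(muscle_on_pelvis) + gravity_transmitted = 0`).
#' @export
hip_reaction <- function(model, state, gravity = TRUE) {
  stopifnot(inherits(model, "muscle_model"), inherits(state, "joint_state"))
  mus <- model$muscles
  per <- purrr::map_dfr(seq_len(nrow(mus)), function(i) {
    m <- as.list(mus[i, ])
    pts <- muscle_path_points(m, state, model)
    seg_lens <- purrr::map_dbl(seq_len(length(pts) - 1L), function(k) {
      sqrt(sum((pts[[k + 1L]] - pts[[k]])^2))
    })
    L <- sum(seg_lens)
    f <- passive_fiber_force(m, L, model$passive_scale)
    # line of action: the path segment that crosses the joint, i.e. the one
    # adjacent to the last pelvis-fixed point (a pelvic via point acts as the
    # effective pulley); the pull on the pelvis points toward the femur
    k <- if (!is.na(m$via_segment) && identical(m$via_segment, "pelvis")) 2L else 1L
    u <- (pts[[k + 1L]] - pts[[k]]) / seg_lens[k]
    tibble(name = m$name, group = m$group, path_length_m = L,
           norm_fiber_length = (L - m$l_ts) / m$l_opt,
           force_N = as.numeric(f),
           ux = u[1L], uy = u[2L], uz = u[3L])
  })
  muscle_on_pelvis <- colSums(per$force_N * as.matrix(per[, c("ux", "uy", "uz")]))
  limb_mass <- model$mass_kg * sum(model$mass_fractions)
  gravity_transmitted <- if (gravity) {
    # limb weight acts along -x (posteriorly, supine); the joint transmits
    # its reversal to the pelvis, so the reaction -(...) carries the weight
    # posteriorly, as the hanging limb drags the head into the cup
    c(model$gravity_m_s2 * limb_mass, 0, 0)
  } else {
    c(0, 0, 0)
  }
  r <- -(muscle_on_pelvis + gravity_transmitted)
  out <- force_vector(r[1L], r[2L], r[3L], frame = "pelvis")
  attr(out, "muscle_forces") <- per
  attr(out, "balance") <- list(
    muscle_on_pelvis = muscle_on_pelvis,
    gravity_transmitted = gravity_transmitted,
    residual = as.numeric(unclass(out)) + muscle_on_pelvis + gravity_transmitted
  )
  out
}

#' Passive flexion sweep of the model
#'
#' Evaluates [hip_reaction()] over a flexion grid with the trial coupling
#' (knee flexion equal to hip flexion, adduction and rotation zero) and
#' reports the joint reaction both as pelvic components and as the reported
#' (posterior, inferior, medial) triple, so model predictions line up with
#' measured trial curves.
#'
#' @param model A [muscle_model()].
#' @param gamma_deg Flexion grid in degrees, within `[0, 90]`.
#' @param knee_coupling Couple knee flexion to hip flexion (the passive
#'   trial protocol); set `FALSE` to keep the knee extended.
#' @param gravity Include gravity.
#' @param side Operated side for the mediolateral sign.
#' @return A `hip_sweep` tibble: `gamma_deg`, pelvic components
#'   `fx_pelvis`, `fy_pelvis`, `fz_pelvis`, reported `posterior_N`,
#'   `inferior_N`, `medial_N`, `resultant_N`; attribute `muscle_forces`
#'   holds the per-muscle force magnitudes per grid point (long tibble).
#' @examples
#' \donttest{
#' sw <- sweep_flexion(scale_model(muscle_model(), 151, 58),
#'                     gamma_deg = seq(0, 90, by = 5))
#' sw$gamma_deg[which.min(sw$resultant_N)]   # interior minimum
#' }
#' @export
sweep_flexion <- function(model, gamma_deg = seq(0, 90, by = 1),
                          knee_coupling = TRUE, gravity = TRUE,
                          side = c("RIGHT", "LEFT")) {
  side <- match.arg(side)
  stopifnot(inherits(model, "muscle_model"))
  if (any(gamma_deg < 0) || any(gamma_deg > 90)) {
    abort("Sweep grid must lie within [0, 90] degrees.")
  }
  med_sign <- if (side == "RIGHT") -1 else 1
  rows <- purrr::map(gamma_deg, function(g) {
    st <- joint_state(g, knee_flexion_deg = if (knee_coupling) g else 0)
    r <- hip_reaction(model, st, gravity = gravity)
    list(reaction = as.numeric(unclass(r)),
         muscles = dplyr::mutate(attr(r, "muscle_forces"), gamma_deg = g,
                                 .before = 1L))
  })
  rmat <- t(vapply(rows, `[[`, numeric(3L), "reaction"))
  out <- tibble(
    gamma_deg = gamma_deg,
    fx_pelvis = rmat[, 1L], fy_pelvis = rmat[, 2L], fz_pelvis = rmat[, 3L],
    posterior_N = -rmat[, 1L],
    inferior_N = rmat[, 3L],
    medial_N = med_sign * rmat[, 2L],
    resultant_N = sqrt(rowSums(rmat^2))
  )
  out <- structure(out, class = c("hip_sweep", class(out)))
  attr(out, "muscle_forces") <- dplyr::bind_rows(purrr::map(rows, "muscles"))
  attr(out, "side") <- side
  out
}

#' Write or read a model sweep as CSV
#'
#' Columns `gamma_deg, posterior_N, inferior_N, medial_N, resultant_N`.
#'
#' @param sweep A `hip_sweep` (or compatible data frame).
#' @param path CSV path.
#' @return The reader returns a tibble; the writer returns `path` invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  cols <- c("gamma_deg", "posterior_N", "inferior_N", "medial_N", "resultant_N")
  stopifnot(all(cols %in% names(sweep)))
  readr::write_csv(dplyr::select(as_tibble(sweep), dplyr::all_of(cols)), path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cols <- c("gamma_deg", "posterior_N", "inferior_N", "medial_N", "resultant_N")
  if (!all(cols %in% names(df))) {
    abort(sprintf("Sweep CSV must have columns %s.", paste(cols, collapse = ", ")))
  }
  structure(df, class = c("hip_sweep", class(df)))
}

#' Compare a model sweep against measured trial curves
#'
#' Builds the mean measured force-versus-flexion curve from a processed
#' trial (averaging the rising limbs of all valid cycles on the sweep's
#' flexion grid), tabulates per-angle differences between model and
#' measurement, and evaluates the qualitative pattern agreements: U-shaped
#' resultant with an interior minimum, posterior component increasing with
#' flexion, superior component decreasing with flexion.
#'
#' @param sweep A `hip_sweep` from [sweep_flexion()].
#' @param summary A `patient_summary` from [run_trial()] (must retain its
#'   sample table), or a data frame with columns `gamma_deg`,
#'   `posterior_N`, `inferior_N`, `medial_N`, `resultant_N`.
#' @return A list: `table` (per-angle model, measured and difference
#'   columns) and `flags` (named logicals of pattern agreement plus the two
#'   minimum locations).
#' @export
compare_model_measured <- function(sweep, summary) {
  stopifnot(inherits(sweep, "data.frame"))
  meas <- measured_mean_curve(summary, sweep$gamma_deg)
  tab <- dplyr::left_join(
    dplyr::rename_with(as_tibble(sweep)[, c("gamma_deg", "posterior_N",
                                            "inferior_N", "medial_N",
                                            "resultant_N")],
                       ~ paste0("model_", .x), -"gamma_deg"),
    dplyr::rename_with(meas, ~ paste0("measured_", .x), -"gamma_deg"),
    by = "gamma_deg")
  tab <- dplyr::mutate(tab,
    diff_resultant_N = .data$model_resultant_N - .data$measured_resultant_N,
    diff_posterior_N = .data$model_posterior_N - .data$measured_posterior_N,
    diff_inferior_N = .data$model_inferior_N - .data$measured_inferior_N)
  flags <- list(
    model_u_shaped = is_u_shaped(sweep$gamma_deg, sweep$resultant_N),
    measured_u_shaped = is_u_shaped(meas$gamma_deg, meas$resultant_N),
    model_posterior_increases = trend_increasing(sweep$gamma_deg, sweep$posterior_N),
    measured_posterior_increases = trend_increasing(meas$gamma_deg, meas$posterior_N),
    model_superior_decreases = trend_increasing(sweep$gamma_deg, sweep$inferior_N),
    measured_superior_decreases = trend_increasing(meas$gamma_deg, meas$inferior_N),
    model_min_gamma_deg = sweep$gamma_deg[which.min(sweep$resultant_N)],
    measured_min_gamma_deg = meas$gamma_deg[which.min(meas$resultant_N)]
  )
  list(table = tab, flags = flags)
}

measured_mean_curve <- function(summary, gamma_grid) {
  cols <- c("posterior_N", "inferior_N", "medial_N", "resultant_N")
  if (is.data.frame(summary) && all(c("gamma_deg", cols) %in% names(summary))) {
    df <- as_tibble(summary)
    seg <- NULL
  } else if (inherits(summary, "patient_summary")) {
    df <- summary$samples
    if (is.null(df)) {
      abort("This patient_summary does not retain its sample table; pass a curve data frame instead.")
    }
    seg <- segment_cycles(df$gamma_deg)
  } else {
    abort("`summary` must be a patient_summary or a per-angle curve data frame.")
  }
  if (!is.null(seg)) {
    df <- dplyr::bind_rows(purrr::pmap(seg, function(cycle, start, end) {
      df[start:end, c("gamma_deg", cols)]
    }))
  }
  purrr::map_dfr(gamma_grid, function(g) {
    out <- purrr::map(cols, function(cl) {
      approx(df$gamma_deg, df[[cl]], xout = g, ties = mean, rule = 2)$y
    })
    tibble(gamma_deg = g, !!!setNames(out, cols))
  })
}

is_u_shaped <- function(gamma, resultant) {
  i <- which.min(resultant)
  i > 1L && i < length(resultant) &&
    resultant[1L] > resultant[i] && resultant[length(resultant)] > resultant[i]
}

# Monotone trend allowing small numerical ripple: fitted slope positive and
# endpoints ordered.
trend_increasing <- function(x, y) {
  stats::coef(stats::lm(y ~ x))[[2L]] > 0 && y[length(y)] > y[1L]
}
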