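#' Reduced passive musculoskeletal model of the hip
#'
#' A rigid-segment model for predicting passive hip joint forces under
#' anaesthesia: the pelvis is fixed to the ground, the femur articulates at
#' the hip through a gimbal joint (flexion, adduction, rotation) and the
#' shank-plus-foot segment through a single-axis knee. Twenty hip-spanning
#' muscles (the broad glutei split into three compartments each) act along
#' polyline paths with optional via points; the short external rotators are
#' omitted, as they are divided by the posterolateral surgical approach.
#' Muscle excitation is zero, so every muscle contributes only its Hill-type
#' passive force; gravity acts posteriorly on the supine patient; inertial
#' terms are excluded because passive trial motion is slow.
#'
#' All coordinates use the pelvic frame (x anterior, y lateral on the
#' operated side, z inferior), with segment-local frames for femur (origin at
#' the hip centre, +z along the shaft toward the knee) and tibia (origin at
#' the knee centre, +z toward the ankle).
#'
#' The generic muscle geometry and Hill parameters ship as a synthetic
#' fixture table (`hip_muscles_generic_synthetic.csv`) whose values were
#' assembled from typical adult lower-limb anatomy; see the methods vignette
#' for its construction and limitations.
#'
#' @param muscles A tibble of muscle definitions (see
#'   [read_muscle_csv()] for the schema). Defaults to the shipped generic
#'   fixture.
#' @param height_cm,mass_kg Anthropometry of the generic model.
#' @param thigh_length_m,shank_length_m Segment lengths of the generic model.
#' @param mass_fractions Segment masses as fractions of body mass (standard
#'   anthropometric coefficients for thigh, shank and foot).
#' @param passive_scale Global multiplier on all passive muscle forces; the
#'   one soft-tissue "stiffness" knob, since per-muscle personalisation is
#'   not identifiable from trial data.
#' @param gravity_m_s2 Gravitational acceleration.
#' @return An object of class `muscle_model`.
#' @export
muscle_model <- function(muscles = NULL,
                         height_cm = 170, mass_kg = 75,
                         thigh_length_m = 0.42, shank_length_m = 0.43,
                         mass_fractions = c(thigh = 0.100, shank = 0.0465,
                                            foot = 0.0145),
                         passive_scale = 1, gravity_m_s2 = 9.81) {
  if (is.null(muscles)) muscles <- read_muscle_csv(default_muscle_fixture())
  muscles <- as_tibble(muscles)
  check_muscle_schema(muscles)
  stopifnot(height_cm > 0, mass_kg > 0, thigh_length_m > 0, shank_length_m > 0,
            all(mass_fractions > 0), passive_scale > 0)
  structure(list(muscles = muscles, height_cm = height_cm, mass_kg = mass_kg,
                 thigh_length_m = thigh_length_m,
                 shank_length_m = shank_length_m,
                 mass_fractions = mass_fractions,
                 passive_scale = passive_scale, gravity_m_s2 = gravity_m_s2),
            class = "muscle_model")
}

default_muscle_fixture <- function() {
  system.file("extdata", "hip_muscles_generic_synthetic.csv",
              package = "hiptension", mustWork = TRUE)
}

muscle_cols <- c("name", "group", "segment_origin", "ox", "oy", "oz",
                 "via_segment", "vx", "vy", "vz",
                 "segment_insertion", "ix", "iy", "iz",
                 "f_iso_max", "l_opt", "l_ts", "k_pe", "eps0")

check_muscle_schema <- function(muscles) {
  if (!all(muscle_cols %in% names(muscles))) {
    abort(sprintf("Muscle table must have columns %s.",
                  paste(muscle_cols, collapse = ", ")))
  }
  if (any(muscles$l_opt <= 0) || any(muscles$l_ts <= 0) ||
      any(muscles$f_iso_max <= 0)) {
    abort("Muscle parameters f_iso_max, l_opt and l_ts must be positive.")
  }
  if (any(!muscles$segment_origin %in% "pelvis")) {
    abort("Every hip-spanning muscle must originate on the pelvis in this model.")
  }
  invisible(muscles)
}

#' Read or write the muscle fixture CSV
#'
#' Schema: `name, group, segment_origin, ox, oy, oz, via_segment, vx, vy,
#' vz, segment_insertion, ix, iy, iz, f_iso_max, l_opt, l_ts, k_pe, eps0`.
#' Coordinates are metres in the owning segment's frame; `via_segment` is
#' empty for straight-line muscles. `group` tags the functional group
#' (flexor, extensor, adductor, abductor) used in diagnostics.
#'
#' @param path CSV path.
#' @param muscles A muscle tibble.
#' @return `read_muscle_csv()` returns a tibble; the writer returns `path`
#'   invisibly.
#' @export
read_muscle_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_muscle_schema(df)
  df
}

#' @rdname read_muscle_csv
#' @export
write_muscle_csv <- function(muscles, path) {
  check_muscle_schema(muscles)
  readr::write_csv(muscles, path, progress = FALSE)
  invisible(path)
}

#' @export
print.muscle_model <- function(x, ...) {
  cat(sprintf(
    "<muscle_model> %d muscle paths, %.0f cm / %.0f kg, passive_scale=%g\n",
    nrow(x$muscles), x$height_cm, x$mass_kg, x$passive_scale))
  invisible(x)
}

#' Scale the generic model to a patient
#'
#' Segment lengths and all attachment coordinates scale isotropically by the
#' patient-to-generic height ratio; segment masses scale by the mass ratio;
#' muscle optimal fibre length and tendon slack length scale with path
#' length (the same length ratio), so the normalised operating range of
#' every muscle is preserved at the reference pose.
#'
#' @param model A [muscle_model()].
#' @param height_cm,mass_kg Patient anthropometry; must be positive.
#' @return A scaled `muscle_model`.
#' @examples
#' m <- muscle_model()
#' scale_model(m, height_cm = 151, mass_kg = 58)  # the modelled patient
#' @export
scale_model <- function(model, height_cm, mass_kg) {
  stopifnot(inherits(model, "muscle_model"))
  if (!is.numeric(height_cm) || height_cm <= 0 ||
      !is.numeric(mass_kg) || mass_kg <= 0) {
    abort("Patient height and mass must be positive.")
  }
  r <- height_cm / model$height_cm
  mus <- dplyr::mutate(model$muscles, dplyr::across(
    dplyr::all_of(c("ox", "oy", "oz", "vx", "vy", "vz",
                    "ix", "iy", "iz", "l_opt", "l_ts")),
    ~ .x * r))
  muscle_model(mus,
               height_cm = height_cm, mass_kg = mass_kg,
               thigh_length_m = model$thigh_length_m * r,
               shank_length_m = model$shank_length_m * r,
               mass_fractions = model$mass_fractions,
               passive_scale = model$passive_scale,
               gravity_m_s2 = model$gravity_m_s2)
}

#' Joint configuration of the hip-knee chain
#'
#' Hip: gimbal joint (flexion about the mediolateral axis, adduction about
#' the anterior axis, internal rotation about the longitudinal axis). Knee:
#' pin joint. The passive trial holds adduction and rotation at zero and
#' couples knee flexion to hip flexion (hip and knee are taken through the
#' range together); `joint_state()` applies that coupling by default.
#'
#' @param hip_flexion_deg Hip flexion in degrees, within `[-10, 120]`.
#' @param hip_adduction_deg,hip_rotation_deg Remaining hip angles (degrees).
#' @param knee_flexion_deg Knee flexion; defaults to `hip_flexion_deg`.
#' @return An object of class `joint_state`.
#' @export
joint_state <- function(hip_flexion_deg, hip_adduction_deg = 0,
                        hip_rotation_deg = 0,
                        knee_flexion_deg = hip_flexion_deg) {
  check_range(hip_flexion_deg, -10, 120)
  structure(list(hip_flexion_deg = hip_flexion_deg,
                 hip_adduction_deg = hip_adduction_deg,
                 hip_rotation_deg = hip_rotation_deg,
                 knee_flexion_deg = knee_flexion_deg),
            class = "joint_state")
}

# Rotation of femur-fixed vectors into the pelvic frame for a joint state.
hip_rotation_matrix <- function(state) {
  rot_y(state$hip_flexion_deg) %*% rot_x(state$hip_adduction_deg) %*%
    rot_z(state$hip_rotation_deg)
}

# Transform a point in a segment frame into the pelvic (ground) frame.
point_in_pelvis <- function(p, segment, state, model) {
  Rh <- hip_rotation_matrix(state)
  switch(segment,
    pelvis = p,
    femur = as.numeric(Rh %*% p),
    tibia = {
      knee <- c(0, 0, model$thigh_length_m)
      Rk <- rot_y(-state$knee_flexion_deg)
      as.numeric(Rh %*% (knee + Rk %*% p))
    },
    abort(sprintf("Unknown segment `%s`.", segment))
  )
}

# Path points of one muscle (row of the muscle table) in the pelvic frame.
muscle_path_points <- function(muscle, state, model) {
  pts <- list(point_in_pelvis(c(muscle$ox, muscle$oy, muscle$oz),
                              muscle$segment_origin, state, model))
  if (!is.na(muscle$via_segment)) {
    pts <- c(pts, list(point_in_pelvis(c(muscle$vx, muscle$vy, muscle$vz),
                                       muscle$via_segment, state, model)))
  }
  c(pts, list(point_in_pelvis(c(muscle$ix, muscle$iy, muscle$iz),
                              muscle$segment_insertion, state, model)))
}

#' Length of a muscle's polyline path at a joint configuration
#'
#' Transforms every attachment point into the ground frame through the
#' current hip and knee poses and sums the Euclidean lengths of the polyline
#' segments. Via points act as frictionless straight-line deviators.
#'
#' @param muscle One row of the muscle table (data frame or list).
#' @param state A [joint_state()].
#' @param model A [muscle_model()].
#' @return Path length in metres.
#' @export
muscle_path_length <- function(muscle, state, model) {
  muscle <- as.list(muscle)
  pts <- muscle_path_points(muscle, state, model)
  sum(purrr::map_dbl(seq_len(length(pts) - 1L), function(i) {
    sqrt(sum((pts[[i + 1L]] - pts[[i]])^2))
  }))
}

#' Hill-type passive fibre force under the rigid-tendon assumption
#'
#' With zero excitation and a rigid tendon, fibre length is path length
#' minus tendon slack length. Below optimal fibre length the passive element
#' is slack and produces no force; beyond it the normalised passive force
#' rises exponentially, reaching the muscle's maximum isometric force at a
#' passive strain of `eps0`:
#' \deqn{F = F_{iso} \frac{e^{k_{pe}(\tilde{l}-1)/\epsilon_0} - 1}{e^{k_{pe}} - 1},
#'   \quad \tilde{l} = (L - l_{ts})/l_{opt} > 1.}
#'
#' @param muscle One row of the muscle table (needs `f_iso_max`, `l_opt`,
#'   `l_ts`, `k_pe`, `eps0`).
#' @param path_length Musculotendon path length in metres.
#' @param passive_scale Global passive-stiffness multiplier.
#' @return Passive force in Newtons (0 when slack; attribute `slack = TRUE`
#'   when the fibre length is non-positive).
#' @export
passive_fiber_force <- function(muscle, path_length, passive_scale = 1) {
  muscle <- as.list(muscle)
  stopifnot(path_length > 0)
  l_f <- path_length - muscle$l_ts
  if (l_f <= 0) {
    return(structure(0, slack = TRUE))
  }
  l_tilde <- l_f / muscle$l_opt
  if (l_tilde <= 1) return(0)
  passive_scale * muscle$f_iso_max *
    (exp(muscle$k_pe * (l_tilde - 1) / muscle$eps0) - 1) / (exp(muscle$k_pe) - 1)
}
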