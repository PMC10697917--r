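#' Force vectors tagged with their coordinate frame
#'
#' A `force_vector` is a 3-component force in Newtons together with the frame
#' it is expressed in: `"head"` for the implant-fixed femoral-head frame O'
#' (the frame the sensor stack measures in) or `"pelvis"` for the body-fixed
#' pelvic frame O.
#'
#' The pelvic frame is right-handed with x anterior, y pointing laterally on
#' the operated side, and z inferior, so that positive rotation about y is
#' anatomical hip flexion, rotation about z is axial (anteversion), and
#' rotations about x are frontal-plane angles (neck inclination, stem varus).
#'
#' @param fx,fy,fz Force components in Newtons; must be finite.
#' @param frame `"head"` or `"pelvis"`.
#' @return An object of class `force_vector`: a named numeric vector of length
#'   3 with a `frame` attribute.
#' @examples
#' force_vector(0, 0, 100, frame = "head")
#' @export
force_vector <- function(fx, fy, fz, frame = c("head", "pelvis")) {
  frame <- match.arg(frame)
  v <- c(fx = fx, fy = fy, fz = fz)
  if (!is.numeric(v) || length(v) != 3L || !all(is.finite(v))) {
    abort("Force components must be three finite numbers.")
  }
  structure(v, frame = frame, class = "force_vector")
}

#' @export
print.force_vector <- function(x, ...) {
  cat(sprintf("<force_vector [%s frame]> fx=%.3f fy=%.3f fz=%.3f N (|F|=%.3f)\n",
              attr(x, "frame"), x[[1L]], x[[2L]], x[[3L]],
              sqrt(sum(unclass(x)^2))))
  invisible(x)
}

force_frame <- function(f) attr(f, "frame") %||% NA_character_

#' Per-patient implant geometry
#'
#' The four angles of the implant-to-pelvis rotation chain, plus the operated
#' side. The stem neck inclination \eqn{\delta} is a property of the stem
#' design (130 degrees for the implant used here); hip flexion \eqn{\gamma}
#' varies through the trial and is supplied per sample, not stored here; stem
#' varus \eqn{\epsilon} and anteversion \eqn{\chi} are patient-specific
#' implantation angles measured radiographically / on CT.
#'
#' @param delta_deg Stem neck inclination in degrees, in `[90, 160]`.
#'   Default 130.
#' @param epsilon_deg Stem varus in degrees, in `[-20, 20]`. Default 2.
#' @param chi_deg Anteversion in degrees, in `[-10, 60]`. Default 20.
#' @param side `"RIGHT"` or `"LEFT"` operated hip.
#' @return An object of class `patient_geometry`.
#' @examples
#' patient_geometry(chi_deg = 15, epsilon_deg = 3)
#' @export
patient_geometry <- function(delta_deg = 130, epsilon_deg = 2, chi_deg = 20,
                             side = c("RIGHT", "LEFT")) {
  side <- match.arg(side)
  check_range(delta_deg, 90, 160)
  check_range(epsilon_deg, -20, 20)
  check_range(chi_deg, -10, 60)
  structure(
    list(delta_deg = delta_deg, epsilon_deg = epsilon_deg,
         chi_deg = chi_deg, side = side),
    class = "patient_geometry"
  )
}

#' @export
print.patient_geometry <- function(x, ...) {
  cat(sprintf(
    "<patient_geometry> delta=%g° epsilon=%g° chi=%g° side=%s\n",
    x$delta_deg, x$epsilon_deg, x$chi_deg, x$side))
  invisible(x)
}

check_range <- function(x, lo, hi, arg = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single finite value in [%g, %g].", arg, lo, hi))
  }
  invisible(x)
}

#' Read or write patient geometry as JSON
#'
#' @param path File path.
#' @param geometry A [patient_geometry()] object.
#' @return `read_geometry_json()` returns a `patient_geometry`;
#'   `write_geometry_json()` returns `path` invisibly.
#' @export
read_geometry_json <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("delta_deg", "epsilon_deg", "chi_deg", "side")) {
    if (is.null(g[[f]])) abort(sprintf("Geometry JSON is missing field `%s`.", f))
  }
  patient_geometry(g$delta_deg, g$epsilon_deg, g$chi_deg, side = g$side)
}

#' @rdname read_geometry_json
#' @export
write_geometry_json <- function(geometry, path) {
  stopifnot(inherits(geometry, "patient_geometry"))
  jsonlite::write_json(unclass(geometry), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Rotate columns of a 3 x n matrix about one axis by a (scalar) angle,
# closed-form, without building the 3x3 matrix. Kept separate from rot_*()
# so the transformation chain and the matrix constructors are independent
# code paths.
rotate_axis <- function(v, axis, angle_deg) {
  a <- deg2rad(angle_deg)
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
    x = rbind(v[1L, , drop = FALSE],
              c_ * v[2L, ] - s_ * v[3L, ],
              s_ * v[2L, ] + c_ * v[3L, ]),
    y = rbind(c_ * v[1L, ] + s_ * v[3L, ],
              v[2L, , drop = FALSE],
              -s_ * v[1L, ] + c_ * v[3L, ]),
    z = rbind(c_ * v[1L, ] - s_ * v[2L, ],
              s_ * v[1L, ] + c_ * v[2L, ],
              v[3L, , drop = FALSE]),
    abort("unknown axis")
  )
}

# Core chain: pelvic F = Ty(gamma) Tz(chi) Tx(epsilon) Tx(delta)^-1 F'.
# The neck-inclination rotation is written in the head (primed) frame, so it
# enters the chain as its inverse. `v` is 3 x n, `gamma_deg` scalar or length n.
pelvis_from_head_mat <- function(v, gamma_deg, geometry) {
  v <- rotate_axis(v, "x", -geometry$delta_deg)
  v <- rotate_axis(v, "x", geometry$epsilon_deg)
  v <- rotate_axis(v, "z", geometry$chi_deg)
  apply_rot_y(v, gamma_deg)
}

head_from_pelvis_mat <- function(v, gamma_deg, geometry) {
  v <- apply_rot_y(v, -gamma_deg)
  v <- rotate_axis(v, "z", -geometry$chi_deg)
  v <- rotate_axis(v, "x", -geometry$epsilon_deg)
  rotate_axis(v, "x", geometry$delta_deg)
}

#' Transform a head-frame force into the pelvic frame
#'
#' Applies the four-rotation chain
#' \deqn{F = T_y(\gamma)\, T_z(\chi)\, T_x(\epsilon)\, T_x(\delta)^{-1} F'}
#' mapping the measured implant-frame force \eqn{F'} into the pelvic frame.
#' The neck-inclination rotation \eqn{T_x(\delta)} is expressed in the head
#' frame and therefore enters the chain as its inverse; the remaining angles
#' (flexion \eqn{\gamma}, anteversion \eqn{\chi}, varus \eqn{\epsilon}) are
#' stated relative to the pelvic frame and apply directly, innermost first.
#' Rotations preserve the force magnitude.
#'
#' @param f_prime A [force_vector()] in the `"head"` frame.
#' @param geometry A [patient_geometry()].
#' @param gamma_deg Hip flexion angle in degrees at this sample, in
#'   `[-10, 120]`.
#' @return A [force_vector()] in the `"pelvis"` frame.
#' @examples
#' g <- patient_geometry(delta_deg = 130, epsilon_deg = 0, chi_deg = 0)
#' head_to_pelvis(force_vector(0, 0, 100, "head"), g, gamma_deg = 0)
#' @export
head_to_pelvis <- function(f_prime, geometry, gamma_deg) {
  if (!inherits(f_prime, "force_vector") || force_frame(f_prime) != "head") {
    abort("`f_prime` must be a force_vector in the \"head\" frame.")
  }
  stopifnot(inherits(geometry, "patient_geometry"))
  check_range(gamma_deg, -10, 120)
  out <- pelvis_from_head_mat(matrix(unclass(f_prime), nrow = 3L),
                              gamma_deg, geometry)
  force_vector(out[1L], out[2L], out[3L], frame = "pelvis")
}

#' Express a pelvic-frame force as the reported component triple
#'
#' The trial reports hip joint forces as (posterior, inferior, medial)
#' components of the force the femoral head exerts on the pelvis, positive
#' when directed posteriorly, inferiorly and medially. In the pelvic frame
#' used here (x anterior, y lateral on the operated side, z inferior) this is
#' `posterior = -fx`, `inferior = +fz`, `medial = -fy`; the operated side only
#' flips the mediolateral sign.
#'
#' @param f A [force_vector()] in the `"pelvis"` frame.
#' @param side `"RIGHT"` or `"LEFT"` operated hip.
#' @return A one-row tibble with columns `posterior_N`, `inferior_N`,
#'   `medial_N`, `resultant_N`.
#' @examples
#' to_reported(force_vector(-10, -5, 20, "pelvis"), side = "RIGHT")
#' @export
to_reported <- function(f, side = c("RIGHT", "LEFT")) {
  side <- match.arg(side)
  if (!inherits(f, "force_vector") || force_frame(f) != "pelvis") {
    abort("`f` must be a force_vector in the \"pelvis\" frame.")
  }
  v <- unclass(f)
  tibble(
    posterior_N = -v[[1L]],
    inferior_N = v[[3L]],
    medial_N = if (side == "RIGHT") -v[[2L]] else v[[2L]],
    resultant_N = sqrt(sum(v^2))
  )
}

# Data-frame verb used by the trial pipeline: takes head-frame component
# columns, adds pelvic components and the reported triple.
add_reported_components <- function(df, geometry) {
  stopifnot(all(c("fx_head", "fy_head", "fz_head", "gamma_deg") %in% names(df)))
  v <- pelvis_from_head_mat(t(as.matrix(df[, c("fx_head", "fy_head", "fz_head")])),
                            df$gamma_deg, geometry)
  med_sign <- if (geometry$side == "RIGHT") -1 else 1
  dplyr::mutate(df,
    fx_pelvis = v[1L, ], fy_pelvis = v[2L, ], fz_pelvis = v[3L, ],
    posterior_N = -.data$fx_pelvis,
    inferior_N = .data$fz_pelvis,
    medial_N = med_sign * .data$fy_pelvis,
    resultant_N = sqrt(.data$fx_pelvis^2 + .data$fy_pelvis^2 + .data$fz_pelvis^2)
  )
}
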