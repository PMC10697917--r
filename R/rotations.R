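#' Elementary rotation matrices
#'
#' Right-handed 3x3 rotation matrices about the x, y and z axes. These are the
#' building blocks of the implant-to-pelvis transformation chain: the frontal
#' plane angles (stem neck inclination, stem varus) rotate about the anterior
#' x axis, hip flexion rotates about the mediolateral y axis, and anteversion
#' rotates about the longitudinal z axis.
#'
#' Angles are taken in degrees at every user-facing interface; conversion to
#' radians happens internally.
#'
#' @param alpha_deg Rotation angle in degrees. Must be a single finite number.
#' @return A 3x3 orthonormal rotation matrix with determinant +1.
#' @examples
#' rot_x(0)                    # identity
#' rot_z(90) %*% c(1, 0, 0)    # maps x onto y
#' @export
rot_x <- function(alpha_deg) {
  a <- deg2rad(check_angle(alpha_deg))
  matrix(c(1, 0, 0,
           0, cos(a), -sin(a),
           0, sin(a), cos(a)), nrow = 3, byrow = TRUE)
}

#' @rdname rot_x
#' @export
rot_y <- function(alpha_deg) {
  a <- deg2rad(check_angle(alpha_deg))
  matrix(c(cos(a), 0, sin(a),
           0, 1, 0,
           -sin(a), 0, cos(a)), nrow = 3, byrow = TRUE)
}

#' @rdname rot_x
#' @export
rot_z <- function(alpha_deg) {
  a <- deg2rad(check_angle(alpha_deg))
  matrix(c(cos(a), -sin(a), 0,
           sin(a), cos(a), 0,
           0, 0, 1), nrow = 3, byrow = TRUE)
}

deg2rad <- function(x) x * pi / 180

check_angle <- function(x, arg = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite angle in degrees.", arg))
  }
  x
}

# Vectorised application of Ry(gamma_i) to columns of a 3 x n matrix,
# avoiding per-sample matrix products in the trial pipeline.
apply_rot_y <- function(v, gamma_deg) {
  a <- deg2rad(gamma_deg)
  c_ <- cos(a); s_ <- sin(a)
  rbind(c_ * v[1L, ] + s_ * v[3L, ],
        v[2L, ],
        -s_ * v[1L, ] + c_ * v[3L, ])
}
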