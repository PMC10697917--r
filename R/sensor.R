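#' Sensor layout of the instrumented femoral head
#'
#' Four pressure sensors sit on the faces of the 14 mm cube inside the 26 mm
#' hemispherical head. Sensor #1 faces the +z' pole of the head frame and
#' measures the Fz' component alone; an opposed pair on the x' axis resolves
#' the one head-frame component whose sign changes during an
#' extension-flexion sweep, and a single sensor on +y' covers the remaining
#' axis, which (like +z') stays compressive under joint load. Each pressure
#' sensor registers compression only.
#'
#' @param normals A 4x3 matrix of unit outward normals in the head frame, one
#'   row per channel. The default is sensor 1 on +z', 2 on +x', 3 on +y',
#'   4 on -x'.
#' @return An object of class `sensor_layout`.
#' @export
sensor_layout <- function(normals = default_normals()) {
  normals <- as.matrix(normals)
  if (!all(dim(normals) == c(4L, 3L))) abort("`normals` must be a 4x3 matrix.")
  lens <- sqrt(rowSums(normals^2))
  if (any(abs(lens - 1) > 1e-9)) abort("Sensor normals must have unit length.")
  if (qr(normals)$rank < 3L) abort("Sensor normals must span all three axes.")
  if (any(abs(normals[1L, ] - c(0, 0, 1)) > 1e-9)) {
    abort("Sensor #1 must face +z' (the pole of the head frame).")
  }
  structure(list(normals = normals, head_diameter_mm = 26, cube_edge_mm = 14),
            class = "sensor_layout")
}

default_normals <- function() {
  matrix(c(0, 0, 1,
           1, 0, 0,
           0, 1, 0,
           -1, 0, 0), nrow = 4L, byrow = TRUE,
         dimnames = list(paste0("s", 1:4), c("x", "y", "z")))
}

#' Sensor noise model
#'
#' Channel noise applied to the (rectified) normal load seen by each sensor:
#' multiplicative Gaussian with standard deviation `mult_sd` of the reading
#' plus additive Gaussian with standard deviation `add_sd_N` Newtons
#' equivalent. Defaults (1 % of reading, 0.5 N) are consistent with the
#' benchtop accuracy of the instrument class.
#'
#' @param mult_sd Multiplicative noise SD as a fraction of the reading.
#' @param add_sd_N Additive noise SD in Newtons equivalent.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(mult_sd = 0.01, add_sd_N = 0.5) {
  stopifnot(is.numeric(mult_sd), mult_sd >= 0, is.numeric(add_sd_N), add_sd_N >= 0)
  structure(list(mult_sd = mult_sd, add_sd_N = add_sd_N), class = "noise_spec")
}

#' Per-channel linear calibration
#'
#' Each channel responds affinely to the normal load on its sensor:
#' `signal = load / gain + offset`, with `gain` in Newtons per signal unit
#' and `offset` in (dimensionless) signal units. All physical meaning of the
#' raw counts enters through the gains.
#'
#' @param gains Numeric vector of 4 positive gains (N per signal unit).
#' @param offsets Numeric vector of 4 signal offsets.
#' @param layout A [sensor_layout()].
#' @param fit Optional per-channel fit diagnostics (kept by [calibrate()]).
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(gains = rep(1, 4), offsets = rep(0, 4),
                              layout = sensor_layout(), fit = NULL) {
  stopifnot(inherits(layout, "sensor_layout"))
  gains <- as.numeric(gains); offsets <- as.numeric(offsets)
  if (length(gains) != 4L || any(!is.finite(gains)) || any(gains <= 0)) {
    abort("`gains` must be 4 positive finite values.")
  }
  if (length(offsets) != 4L || any(!is.finite(offsets))) {
    abort("`offsets` must be 4 finite values.")
  }
  structure(list(gains = gains, offsets = offsets, layout = layout, fit = fit),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model>\n")
  cat("  gains   (N/unit):", paste(signif(x$gains, 6), collapse = ", "), "\n")
  cat("  offsets (units) :", paste(signif(x$offsets, 6), collapse = ", "), "\n")
  if (!is.null(x$fit)) cat("  fitted from", x$fit$n_loads[1L], "calibration loads\n")
  invisible(x)
}

# Internal: forward-project a 3 x n matrix of head-frame forces into raw
# channel signals (n x 4). Rectified normal loads, then noise, then gain/offset.
project_forces_mat <- function(fmat, cal, noise = noise_spec(0, 0)) {
  n <- ncol(fmat)
  loads <- pmax(cal$layout$normals %*% fmat, 0)        # 4 x n, Newtons
  if (noise$mult_sd > 0 || noise$add_sd_N > 0) {
    loads <- loads * (1 + matrix(rnorm(4L * n, 0, noise$mult_sd), 4L, n)) +
      matrix(rnorm(4L * n, 0, noise$add_sd_N), 4L, n)
  }
  t(loads / cal$gains + cal$offsets)
}

#' Forward model: project a head-frame force onto the sensor channels
#'
#' Computes the rectified normal load on each sensor, `max(0, n_i . F')`
#' (pressure sensors register compression only), applies the noise model to
#' the load, and converts to raw signal units through the channel gain and
#' offset. Deterministic given `rng_seed`.
#'
#' @param f_prime A [force_vector()] in the `"head"` frame.
#' @param cal A [calibration_model()].
#' @param noise A [noise_spec()]; default is noiseless.
#' @param rng_seed Optional integer seed for the noise draws.
#' @param t Sample time in seconds.
#' @return A one-row tibble with columns `t`, `s1`..`s4` (a channel sample).
#' @examples
#' cal <- calibration_model()
#' project_force(force_vector(0, 0, 100, "head"), cal)
#' @export
project_force <- function(f_prime, cal, noise = noise_spec(0, 0),
                          rng_seed = NULL, t = 0) {
  if (!inherits(f_prime, "force_vector") || force_frame(f_prime) != "head") {
    abort("`f_prime` must be a force_vector in the \"head\" frame.")
  }
  stopifnot(inherits(cal, "calibration_model"), inherits(noise, "noise_spec"))
  s <- local_seed(rng_seed,
                  project_forces_mat(matrix(unclass(f_prime), nrow = 3L), cal, noise))
  tibble(t = t, s1 = s[1L, 1L], s2 = s[1L, 2L], s3 = s[1L, 3L], s4 = s[1L, 4L])
}

# Internal inverse map: raw signals (n x 4) -> head-frame forces (3 x n).
# De-offset and scale to normal loads, then solve the rectified 4-channel ->
# 3-component mapping: for this layout (orthonormal one-sided axes with an
# opposed pair on x') the least-squares solution honouring compression-only
# rectification is the signed sum of channel loads along each axis, N^T l.
reconstruct_forces_mat <- function(smat, cal) {
  loads <- t((t(smat) - cal$offsets) * cal$gains)      # n x 4, Newtons
  t(loads %*% cal$layout$normals)                      # 3 x n
}

#' Inverse model: reconstruct the head-frame force from a channel sample
#'
#' De-offsets and rescales each channel to the normal load on its sensor and
#' solves the overdetermined four-sensor mapping for the three force
#' components, honouring the compression-only rectification: the opposed
#' pair on x' contributes its signed difference, the single +y' and +z'
#' sensors their loads directly.
#'
#' @param sample A one-row data frame with columns `s1`..`s4` (see
#'   [project_force()]), or a named numeric vector.
#' @param cal A [calibration_model()].
#' @return A [force_vector()] in the `"head"` frame. If every channel is at or
#'   below its offset the zero force is returned with attribute
#'   `no_load = TRUE`.
#' @export
reconstruct_force <- function(sample, cal) {
  stopifnot(inherits(cal, "calibration_model"))
  if (is.data.frame(sample)) {
    stopifnot(nrow(sample) == 1L, all(paste0("s", 1:4) %in% names(sample)))
    s <- as.numeric(sample[1L, paste0("s", 1:4)])
  } else {
    s <- as.numeric(sample[paste0("s", 1:4)])
  }
  if (any(!is.finite(s))) abort("Channel signals must be finite.")
  if (all(s <= cal$offsets)) {
    f <- force_vector(0, 0, 0, frame = "head")
    attr(f, "no_load") <- TRUE
    return(f)
  }
  v <- reconstruct_forces_mat(matrix(s, nrow = 1L), cal)
  force_vector(v[1L], v[2L], v[3L], frame = "head")
}

# Tibble verb: add reconstructed head-frame force columns to a sensor log.
reconstruct_forces <- function(df, cal) {
  stopifnot(all(paste0("s", 1:4) %in% names(df)))
  v <- reconstruct_forces_mat(as.matrix(df[, paste0("s", 1:4)]), cal)
  dplyr::mutate(df, fx_head = v[1L, ], fy_head = v[2L, ], fz_head = v[3L, ])
}

#' Fit per-channel gains and offsets from benchtop calibration loads
#'
#' The benchtop protocol loads the assembled head from three-dimensional
#' directions on a materials-testing machine; output signals are linearly
#' related to the applied force. For every channel this fits
#' `signal ~ applied normal load` by ordinary least squares and inverts the
#' slope to a gain. A channel whose applied normal loads do not vary over the
#' protocol cannot be identified and is flagged (`NA` gain).
#'
#' @param loads A data frame with columns `magnitude_N`, `theta_deg`,
#'   `phi_deg`: load magnitude and spherical direction in the head frame
#'   (polar angle `theta` from the +z' pole, azimuth `phi` from +x').
#' @param samples A data frame of the matching raw signals, columns
#'   `s1`..`s4`, one row per load.
#' @param layout A [sensor_layout()].
#' @return A [calibration_model()] whose `fit` field holds per-channel
#'   diagnostics (slope, intercept, residual SD, number of distinct loads).
#' @export
calibrate <- function(loads, samples, layout = sensor_layout()) {
  loads <- as_tibble(loads); samples <- as_tibble(samples)
  stopifnot(all(c("magnitude_N", "theta_deg", "phi_deg") %in% names(loads)),
            all(paste0("s", 1:4) %in% names(samples)),
            nrow(loads) == nrow(samples))
  if (nrow(loads) < 2L) abort("Need at least two calibration loads.")
  fmat <- t(spherical_force(loads$magnitude_N, loads$theta_deg, loads$phi_deg))
  applied <- t(pmax(layout$normals %*% fmat, 0))       # n x 4
  if (max(apply(applied, 2L, function(a) length(unique(round(a, 9))))) < 2L) {
    abort("Rank-deficient calibration design: applied loads are identical on every channel.")
  }
  fit <- purrr::map_dfr(1:4, function(i) {
    a <- applied[, i]; s <- samples[[paste0("s", i)]]
    n_lev <- length(unique(round(a, 9)))
    if (n_lev < 2L) {
      return(tibble(channel = i, gain = NA_real_, offset = NA_real_,
                    residual_sd = NA_real_, n_levels = n_lev, n_loads = length(a)))
    }
    co <- stats::coef(m <- stats::lm(s ~ a))
    tibble(channel = i, gain = 1 / co[[2L]], offset = co[[1L]],
           residual_sd = stats::sd(stats::residuals(m)),
           n_levels = n_lev, n_loads = length(a))
  })
  if (all(is.na(fit$gain))) abort("No channel could be calibrated.")
  gains <- fit$gain; offsets <- fit$offset
  # unidentified channels keep a unit gain / zero offset but stay flagged in `fit`
  offsets[is.na(offsets)] <- 0
  gains[is.na(gains)] <- 1
  calibration_model(gains, offsets, layout, fit = fit)
}

spherical_force <- function(magnitude_N, theta_deg, phi_deg) {
  th <- deg2rad(theta_deg); ph <- deg2rad(phi_deg)
  cbind(magnitude_N * sin(th) * cos(ph),
        magnitude_N * sin(th) * sin(ph),
        magnitude_N * cos(th))
}

#' Simulate the benchtop calibration accuracy benchmark
#'
#' Sweeps the benchtop protocol grid -- polar angle theta from 30 to 90
#' degrees and azimuth phi from 0 to 45 degrees in 15-degree increments,
#' three repetitions, magnitudes 50 to 800 N in 150 N steps (bracketing the
#' intraoperative range) -- projecting every load through the sensor forward
#' model with the given noise and reconstructing it, and summarises accuracy
#' as the mean absolute force-magnitude error (percent) and the mean
#' absolute angular error (degrees) between true and reconstructed vectors.
#'
#' @param cal A [calibration_model()].
#' @param noise A [noise_spec()]; `noise_spec(0, 0)` gives exact recovery.
#' @param seed Integer seed for the noise draws.
#' @param magnitudes_N Load magnitudes swept (Newtons).
#' @param reps Repetitions of the angular grid.
#' @return A one-row tibble: `mean_abs_magnitude_error_pct`,
#'   `mean_abs_angle_error_deg`, `n_loads`.
#' @examples
#' run_calibration_benchmark(calibration_model(), noise_spec(0, 0), seed = 1)
#' @export
run_calibration_benchmark <- function(cal = calibration_model(),
                                      noise = noise_spec(), seed = 1,
                                      magnitudes_N = seq(50, 800, by = 150),
                                      reps = 3) {
  stopifnot(inherits(cal, "calibration_model"), inherits(noise, "noise_spec"))
  grid <- tidyr::expand_grid(theta_deg = seq(30, 90, by = 15),
                             phi_deg = seq(0, 45, by = 15),
                             magnitude_N = magnitudes_N,
                             rep = seq_len(reps))
  truth <- t(spherical_force(grid$magnitude_N, grid$theta_deg, grid$phi_deg))
  rec <- local_seed(seed, {
    smat <- project_forces_mat(truth, cal, noise)
    reconstruct_forces_mat(smat, cal)
  })
  mag_t <- sqrt(colSums(truth^2)); mag_r <- sqrt(colSums(rec^2))
  cosang <- pmin(1, pmax(-1, colSums(truth * rec) / (mag_t * mag_r)))
  tibble(
    mean_abs_magnitude_error_pct = mean(abs(mag_r - mag_t) / mag_t) * 100,
    mean_abs_angle_error_deg = mean(acos(cosang)) * 180 / pi,
    n_loads = nrow(grid)
  )
}

#' @exportS3Method generics::tidy
tidy.calibration_model <- function(x, ...) {
  if (!is.null(x$fit)) {
    dplyr::select(x$fit, "channel", "gain", "offset", "residual_sd", "n_levels")
  } else {
    tibble(channel = 1:4, gain = x$gains, offset = x$offsets,
           residual_sd = NA_real_, n_levels = NA_integer_)
  }
}

#' @exportS3Method generics::glance
glance.calibration_model <- function(x, ...) {
  tibble(
    n_channels = 4L,
    n_identified = if (is.null(x$fit)) 4L else sum(!is.na(x$fit$gain)),
    mean_residual_sd = if (is.null(x$fit)) NA_real_ else
      mean(x$fit$residual_sd, na.rm = TRUE)
  )
}

#' Read or write a calibration model as JSON
#'
#' @param cal A [calibration_model()].
#' @param path File path.
#' @return `read_calibration_json()` returns a `calibration_model`;
#'   `write_calibration_json()` returns `path` invisibly.
#' @export
write_calibration_json <- function(cal, path) {
  stopifnot(inherits(cal, "calibration_model"))
  jsonlite::write_json(
    list(gains = cal$gains, offsets = cal$offsets,
         normals = cal$layout$normals),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_model(x$gains, x$offsets, sensor_layout(matrix(unlist(x$normals), 4L, 3L)))
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards; with seed = NULL the current stream is used.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
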