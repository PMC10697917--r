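test_that("forward projection follows the rectified affine channel model", {
  cal <- unit_cal()
  # zero force, zero noise: every channel sits at its offset
  cal2 <- calibration_model(gains = c(1, 2, 4, 5), offsets = c(0.1, -0.2, 0.3, 0))
  s <- project_force(force_vector(0, 0, 0, "head"), cal2)
  expect_equal(as.numeric(s[, paste0("s", 1:4)]), cal2$offsets)

  # axis-aligned load excites only the matching channel
  s <- project_force(force_vector(0, 0, 100, "head"), cal)
  expect_equal(as.numeric(s[, paste0("s", 1:4)]), c(100, 0, 0, 0))
  s <- project_force(force_vector(-80, 0, 0, "head"), cal)
  expect_equal(as.numeric(s[, paste0("s", 1:4)]), c(0, 0, 0, 80))
})

test_that("noiseless project-reconstruct round trip is exact in the sensed region", {
  cal <- calibration_model(gains = c(0.5, 1, 2, 1.5),
                           offsets = c(1, 2, 3, 4))
  fmat <- random_envelope_forces(200)
  # add negative-x cases: the opposed pair must resolve the sign
  fmat <- rbind(fmat, fmat %*% diag(c(-1, 1, 1)))
  for (i in seq_len(nrow(fmat))) {
    f <- force_vector(fmat[i, 1], fmat[i, 2], fmat[i, 3], "head")
    rec <- reconstruct_force(project_force(f, cal), cal)
    expect_lt(max(abs(unclass(rec) - unclass(f))), 1e-9)
  }
})

test_that("all-channels-at-offset reconstructs to a flagged zero force", {
  cal <- calibration_model(offsets = c(5, 5, 5, 5))
  rec <- reconstruct_force(tibble::tibble(s1 = 5, s2 = 4.5, s3 = 5, s4 = 4.9), cal)
  expect_equal(fv((rec)), c(0, 0, 0))
  expect_true(isTRUE(attr(rec, "no_load")))
})

test_that("calibration recovers known gains and offsets", {
  true_cal <- calibration_model(gains = c(0.5, 1, 2, 1.5),
                                offsets = c(0.3, 0, -0.5, 1))
  # protocol grid extended with -x directions so channel 4 is excited too
  loads <- tidyr::expand_grid(theta_deg = seq(30, 90, 15),
                              phi_deg = c(seq(0, 45, 15), 135, 180),
                              magnitude_N = c(100, 300, 500))
  smat <- t(sapply(seq_len(nrow(loads)), function(i) {
    f <- loads$magnitude_N[i] *
      c(sinpi(loads$theta_deg[i] / 180) * cospi(loads$phi_deg[i] / 180),
        sinpi(loads$theta_deg[i] / 180) * sinpi(loads$phi_deg[i] / 180),
        cospi(loads$theta_deg[i] / 180))
    as.numeric(project_force(force_vector(f[1], f[2], f[3], "head"),
                             true_cal)[, paste0("s", 1:4)])
  }))
  colnames(smat) <- paste0("s", 1:4)
  fit <- calibrate(loads, as.data.frame(smat))
  expect_equal(fit$gains, true_cal$gains, tolerance = 1e-9)
  expect_equal(fit$offsets, true_cal$offsets, tolerance = 1e-9)

  # broom-style accessors
  expect_equal(nrow(tidy(fit)), 4L)
  expect_equal(glance(fit)$n_identified, 4L)
})

test_that("a two-point exact fit gives gain 2 and offset 0", {
  loads <- tibble::tibble(magnitude_N = c(100, 200), theta_deg = 0, phi_deg = 0)
  sig <- tibble::tibble(s1 = c(50, 100), s2 = 0, s3 = 0, s4 = 0)
  fit <- calibrate(loads, sig)
  expect_equal(fit$gains[1], 2)
  expect_equal(fit$offsets[1], 0)
  # unexcited channels are flagged, not invented
  expect_true(all(is.na(tidy(fit)$gain[2:4])))
})

test_that("degenerate calibration designs are rejected with a diagnostic", {
  loads <- tibble::tibble(magnitude_N = rep(100, 5), theta_deg = 45, phi_deg = 20)
  sig <- tibble::tibble(s1 = rep(70.7, 5), s2 = rep(57.7, 5),
                        s3 = rep(21, 5), s4 = rep(0, 5))
  expect_error(calibrate(loads, sig), "Rank-deficient")
  expect_error(calibrate(loads[1, ], sig[1, ]), "two calibration loads")
})

test_that("noisy protocol calibration recovers gains within 2 percent", {
  true_cal <- calibration_model(gains = c(0.5, 1, 2, 1.5))
  loads <- tidyr::expand_grid(theta_deg = seq(30, 90, 15),
                              phi_deg = c(seq(0, 45, 15), 160, 200),
                              magnitude_N = seq(50, 800, 150),
                              rep = 1:3)
  fmat <- with(loads, cbind(magnitude_N * sinpi(theta_deg / 180) * cospi(phi_deg / 180),
                            magnitude_N * sinpi(theta_deg / 180) * sinpi(phi_deg / 180),
                            magnitude_N * cospi(theta_deg / 180)))
  smat <- hiptension:::local_seed(99,
    hiptension:::project_forces_mat(t(fmat), true_cal, noise_spec()))
  colnames(smat) <- paste0("s", 1:4)
  fit <- calibrate(loads, as.data.frame(smat))
  expect_lt(max(abs(fit$gains / true_cal$gains - 1)), 0.02)
})

test_that("the benchtop benchmark is exact without noise and error grows with noise", {
  cal <- unit_cal()
  clean <- run_calibration_benchmark(cal, noise_spec(0, 0), seed = 1)
  expect_lt(clean$mean_abs_magnitude_error_pct, 1e-10)
  expect_lt(clean$mean_abs_angle_error_deg, 1e-5)  # acos() noise near 1
  expect_equal(clean$n_loads, 5L * 4L * 6L * 3L)

  errs <- sapply(c(0.005, 0.02, 0.08), function(m) {
    run_calibration_benchmark(cal, noise_spec(mult_sd = m, add_sd_N = 0.5),
                              seed = 5)$mean_abs_magnitude_error_pct
  })
  expect_true(all(diff(errs) > 0))
})

test_that("calibration models round-trip through JSON", {
  cal <- calibration_model(gains = c(0.5, 1, 2, 1.5), offsets = c(1, 0, -1, 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(cal, path)
  back <- read_calibration_json(path)
  expect_equal(back$gains, cal$gains)
  expect_equal(back$offsets, cal$offsets)
  expect_equal(back$layout$normals, unname(cal$layout$normals))
})
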