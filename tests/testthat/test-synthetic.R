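test_that("truth trajectories hit their anchors exactly and recombine exactly", {
  spec <- quick_spec()
  g <- c(0, spec$gamma_min_deg, 90, seq(0, 90, by = 1))
  tr <- truth_trajectory(spec, g)
  expect_equal(tr$resultant_N[1], spec$f_ext_N)
  expect_equal(tr$resultant_N[2], spec$f_min_N)
  expect_equal(tr$resultant_N[3], spec$f_90_N)
  # component Pythagorean identity at every grid point
  expect_equal(sqrt(tr$posterior_N^2 + tr$inferior_N^2 + tr$medial_N^2),
               tr$resultant_N, tolerance = 1e-12)
  expect_equal(sqrt(tr$fx_pelvis^2 + tr$fy_pelvis^2 + tr$fz_pelvis^2),
               tr$resultant_N, tolerance = 1e-12)
  # the minimum never undershoots the anchor (shape preservation)
  expect_gte(min(tr$resultant_N), spec$f_min_N - 1e-12)
})

test_that("summarising the noiseless truth recovers the spec anchors", {
  spec <- quick_spec()
  tr <- truth_trajectory(spec, seq(0, 90, by = 0.1))
  s <- summarize_cycle(tr$resultant_N, tr$gamma_deg)
  expect_equal(s$max_force_N, spec$f_ext_N, tolerance = 1e-6)
  expect_equal(s$min_force_N, spec$f_min_N, tolerance = 1e-6)
  expect_equal(s$gamma_at_min_deg, spec$gamma_min_deg, tolerance = 0.1)
  expect_equal(s$force_at_90_N, spec$f_90_N, tolerance = 1e-6)
})

test_that("the generator respects the measured qualitative component behaviour", {
  tr <- truth_trajectory(quick_spec(), 0:90)
  expect_true(all(diff(tr$posterior_N) > -1e-9))
  expect_true(all(diff(tr$inferior_N) > -1e-9))
  # mediolateral component varies by less than 20 % over the sweep
  expect_lt(diff(range(tr$medial_N)) / mean(abs(tr$medial_N)), 0.2)
})

test_that("invalid virtual patient specs are rejected", {
  expect_error(virtual_patient_spec(f_min_N = 200, f_90_N = 155.1),
               "must not exceed")
  expect_error(virtual_patient_spec(gamma_min_deg = 0), "inside")
  expect_error(virtual_patient_spec(gamma_min_deg = 95), "inside")
  expect_error(virtual_patient_spec(f_ext_N = -5), "positive")
})

test_that("recordings are deterministic given a seed", {
  spec <- quick_spec(noise = noise_spec(), seed = 123)
  a <- generate_recording(spec)
  b <- generate_recording(spec)
  expect_identical(as.data.frame(a$recording), as.data.frame(b$recording))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_sensor_log(a$recording, p1)
  write_sensor_log(b$recording, p2)
  expect_identical(readLines(p1), readLines(p2))
  # a different seed gives different noise
  c_ <- generate_recording(quick_spec(noise = noise_spec(), seed = 124))
  expect_false(identical(a$recording$s1, c_$recording$s1))
})

test_that("full-loop recovery: within 1 % noiseless, within 5 % at default noise", {
  clean <- generate_recording(quick_spec(seed = 5))
  ps <- run_trial(clean$recording, unit_cal())
  rel <- abs(ps$metrics$mean / as.numeric(clean$truth[1, ps$metrics$metric]) - 1)
  expect_true(all(rel < 0.01))

  noisy <- generate_recording(quick_spec(noise = noise_spec(), seed = 6))
  psn <- run_trial(noisy$recording, unit_cal())
  met <- psn$metrics
  for (m in c("max_force_N", "min_force_N", "force_at_90_N")) {
    truth_m <- noisy$truth[[m]][1]
    expect_lt(abs(met$mean[met$metric == m] / truth_m - 1), 0.05, label = m)
  }
  # the flexion angle of the minimum sits in a flat basin; judge it on the
  # sweep's full scale (5% of 90 degrees)
  expect_lt(abs(met$mean[met$metric == "gamma_at_min_deg"] -
                  noisy$truth$gamma_at_min_deg[1]), 4.5)
})

test_that("a degenerate cohort has zero intersubject COV", {
  cs <- cohort_spec(n_patients = 3, cvs = c(f_ext_N = 0, f_min_N = 0,
                                            gamma_min_deg = 0, f_90_N = 0),
                    noise = noise_spec(0, 0), seed = 2)
  sim <- generate_cohort(cs)
  stats <- cohort_stats(dplyr::rename(sim$truth, max_force_N = "max_force_N"))
  expect_true(all(stats$intersubject_cov_pct < 1e-9))
  expect_equal(nrow(sim$truth), 3L)
})

test_that("log-normal cohort draws reproduce the analytic coefficient of variation", {
  # CV of a log-normal with sdlog s is sqrt(exp(s^2)-1); the generator is
  # parameterised so that this equals the requested cv exactly
  draws <- hiptension:::local_seed(17,
    hiptension:::rlnorm_mean_cv(4000, mean = 120, cv = 0.3))
  expect_equal(mean(draws), 120, tolerance = 0.02)
  expect_equal(sd(draws) / mean(draws), 0.3, tolerance = 0.05)

  # end-to-end: moderate cohort, empirical truth-table CV near nominal
  cs <- cohort_spec(n_patients = 50,
                    cvs = c(f_ext_N = 0.3, f_min_N = 0.3,
                            gamma_min_deg = 0.2, f_90_N = 0.3),
                    means = c(f_ext_N = 418.7, f_min_N = 120.0,
                              gamma_min_deg = 32.8, f_90_N = 204.5),
                    noise = noise_spec(0, 0), seed = 9)
  sim <- generate_cohort(cs)
  emp_cv <- cov_pct(sim$truth$min_force_N) / 100
  expect_lt(abs(emp_cv - 0.3), 0.1)
})

test_that("cohort recordings carry distinct patients and valid specs", {
  cs <- cohort_spec(n_patients = 3, noise = noise_spec(0, 0), seed = 4)
  sim <- generate_cohort(cs)
  ids <- vapply(sim$patients, function(p) attr(p$recording, "patient_id"), "")
  expect_equal(length(unique(ids)), 3L)
  for (p in sim$patients) {
    expect_s3_class(p$spec, "virtual_patient_spec")
    expect_lte(p$spec$f_min_N, min(p$spec$f_ext_N, p$spec$f_90_N))
  }
})
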