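# The default model is read once; tests treat it as immutable.
generic_model <- muscle_model()
patient_model <- scale_model(generic_model, height_cm = 151, mass_kg = 58)

test_that("model scaling is a similarity transform with mass-ratio masses", {
  same <- scale_model(generic_model, generic_model$height_cm,
                      generic_model$mass_kg)
  expect_equal(same$muscles, generic_model$muscles)
  expect_equal(same$thigh_length_m, generic_model$thigh_length_m)

  up <- scale_model(generic_model, generic_model$height_cm * 1.1,
                    generic_model$mass_kg)
  st <- joint_state(0)
  for (i in c(1, 5, 12, 20)) {
    expect_equal(muscle_path_length(up$muscles[i, ], st, up),
                 1.1 * muscle_path_length(generic_model$muscles[i, ], st,
                                          generic_model),
                 tolerance = 1e-9)
  }

  # the modelled patient: masses scale by the mass ratio
  expect_equal(patient_model$mass_kg * sum(patient_model$mass_fractions),
               58 / 75 * generic_model$mass_kg * sum(generic_model$mass_fractions))
  expect_error(scale_model(generic_model, -151, 58), "positive")
})

test_that("path lengths agree with an explicit rigid-transform oracle", {
  st0 <- joint_state(0)
  m <- generic_model$muscles[generic_model$muscles$name == "glut_max2", ]
  d0 <- sqrt(sum((c(m$ix, m$iy, m$iz) - c(m$ox, m$oy, m$oz))^2))
  expect_equal(muscle_path_length(m, st0, generic_model), d0, tolerance = 1e-12)

  # flexion rotates the femur-fixed insertion about the hip centre
  for (g in c(15, 40, 75)) {
    p_ins <- as.numeric(rot_y(g) %*% c(m$ix, m$iy, m$iz))
    want <- sqrt(sum((p_ins - c(m$ox, m$oy, m$oz))^2))
    expect_equal(muscle_path_length(m, joint_state(g), generic_model), want,
                 tolerance = 1e-12)
  }

  # a collinear via point leaves the length unchanged
  m2 <- m
  m2$via_segment <- "pelvis"
  mid <- 0.5 * (c(m$ox, m$oy, m$oz) + c(m$ix, m$iy, m$iz))
  m2$vx <- mid[1]; m2$vy <- mid[2]; m2$vz <- mid[3]
  expect_equal(muscle_path_length(m2, st0, generic_model),
               muscle_path_length(m, st0, generic_model), tolerance = 1e-12)
})

test_that("the passive force-length curve has the Hill end points and is monotone", {
  m <- list(f_iso_max = 500, l_opt = 0.1, l_ts = 0.2, k_pe = 4, eps0 = 0.6)
  expect_equal(passive_fiber_force(m, 0.2 + 0.1), 0)           # l_tilde = 1
  expect_equal(passive_fiber_force(m, 0.2 + 0.1 * 1.6), 500)   # l_tilde = 1+eps0
  expect_lt(passive_fiber_force(m, 0.25), 1e-12)               # below optimal
  slack <- passive_fiber_force(m, 0.15)                        # fibre length <= 0
  expect_equal(as.numeric(slack), 0)
  expect_true(isTRUE(attr(slack, "slack")))
  lt <- seq(1.001, 1.6, length.out = 50)
  f <- sapply(lt, function(l) passive_fiber_force(m, 0.2 + 0.1 * l))
  expect_true(all(diff(f) > 0))
  # global passive-stiffness multiplier is linear
  expect_equal(passive_fiber_force(m, 0.33, passive_scale = 2),
               2 * passive_fiber_force(m, 0.33))
})

test_that("hip reaction balances muscles and gravity exactly", {
  # all muscles slack and gravity off: zero reaction
  r0 <- hip_reaction(patient_model, joint_state(32), gravity = FALSE)
  # mid-flexion: small forces; force balance still exact
  bal <- attr(r0, "balance")
  expect_lt(max(abs(bal$residual)), 1e-9)

  # gravity-only: reaction equals the hanging limb weight, directed posteriorly
  slack_model <- patient_model
  slack_model$muscles$l_ts <- 2
  rg <- hip_reaction(slack_model, joint_state(45), gravity = TRUE)
  w <- 58 * sum(patient_model$mass_fractions) * 9.81
  expect_equal(sqrt(sum(unclass(rg)^2)), w, tolerance = 1e-9)
  expect_equal(fv((rg)), c(-w, 0, 0), tolerance = 1e-9)
  rg0 <- hip_reaction(slack_model, joint_state(45), gravity = FALSE)
  expect_equal(fv((rg0)), c(0, 0, 0))

  # single straight muscle with known geometry: hand-computed closed form
  one <- patient_model$muscles[patient_model$muscles$name == "add_long", ][1, ]
  mono_model <- patient_model
  mono_model$muscles <- one
  st <- joint_state(0)
  L <- muscle_path_length(one, st, mono_model)
  f <- passive_fiber_force(one, L)
  u <- (c(one$ix, one$iy, one$iz) - c(one$ox, one$oy, one$oz)) / L
  want <- -f * u
  got <- hip_reaction(mono_model, st, gravity = FALSE)
  expect_equal(fv((got)), want, tolerance = 1e-9)
})

test_that("antagonistic stretch: extensors lengthen in flexion, flexors in extension", {
  mus <- generic_model$muscles
  g <- seq(0, 90, by = 5)
  for (i in seq_len(nrow(mus))) {
    l <- sapply(g, function(x)
      muscle_path_length(mus[i, ], joint_state(x), generic_model))
    if (mus$group[i] == "extensor") expect_true(all(diff(l) > -1e-9),
                                                label = mus$name[i])
    if (mus$group[i] == "flexor") expect_true(all(diff(l) < 1e-9),
                                              label = mus$name[i])
  }
})

test_that("the passive sweep is U-shaped with the measured pattern directions", {
  sw <- sweep_flexion(patient_model, gamma_deg = seq(0, 90, by = 2))
  i_min <- which.min(sw$resultant_N)
  g_min <- sw$gamma_deg[i_min]
  expect_gt(g_min, 10)
  expect_lt(g_min, 50)
  expect_gt(sw$resultant_N[1], sw$resultant_N[i_min])
  expect_gt(sw$resultant_N[nrow(sw)], sw$resultant_N[i_min])
  # posterior grows, superior fades with flexion (trend over the sweep)
  expect_true(hiptension:::trend_increasing(sw$gamma_deg, sw$posterior_N))
  expect_true(hiptension:::trend_increasing(sw$gamma_deg, sw$inferior_N))
})

test_that("doubling every muscle strength doubles the muscle contribution", {
  strong <- patient_model
  strong$muscles$f_iso_max <- 2 * strong$muscles$f_iso_max
  for (g in c(0, 45, 90)) {
    a <- hip_reaction(patient_model, joint_state(g), gravity = FALSE)
    b <- hip_reaction(strong, joint_state(g), gravity = FALSE)
    expect_equal(fv((b)), 2 * fv((a)), tolerance = 1e-9)
  }
})

test_that("model and synthetic measurement agree on pattern flags", {
  sw <- sweep_flexion(patient_model, gamma_deg = seq(0, 90, by = 3))
  sim <- generate_recording(quick_spec(), patient_id = "cmp")
  ps <- run_trial(sim$recording, unit_cal())
  cmp <- compare_model_measured(sw, ps)
  expect_true(cmp$flags$model_u_shaped)
  expect_true(cmp$flags$measured_u_shaped)
  expect_true(cmp$flags$model_posterior_increases)
  expect_true(cmp$flags$measured_posterior_increases)
  expect_true(cmp$flags$model_superior_decreases)
  expect_true(cmp$flags$measured_superior_decreases)
  expect_equal(nrow(cmp$table), nrow(sw))
  expect_true(all(is.finite(cmp$table$diff_resultant_N)))
})
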