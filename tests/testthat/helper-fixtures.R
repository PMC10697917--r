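# Shared fixtures: everything is generated in code at test time.

unit_cal <- function() calibration_model()

# Random force directions inside the benchtop calibration envelope
# (theta in [30, 90] from the +z' pole, phi in [0, 45]), magnitudes in Newtons.
random_envelope_forces <- function(n, seed = 42) {
  set.seed(seed)
  th <- runif(n, 30, 90) * pi / 180
  ph <- runif(n, 0, 45) * pi / 180
  mag <- runif(n, 50, 800)
  cbind(mag * sin(th) * cos(ph), mag * sin(th) * sin(ph), mag * cos(th))
}

# Geometry with all chain angles zero (bypasses the clinical plausibility
# bounds on purpose: the mathematical identity of the chain is what is
# under test).
zero_geometry <- function() {
  structure(list(delta_deg = 0, epsilon_deg = 0, chi_deg = 0, side = "RIGHT"),
            class = "patient_geometry")
}

# Independent oracle for the transformation chain: explicit 3x3 matrix
# products built from the printed rotation layouts (the implementation uses
# closed-form per-axis vector rotations instead).
oracle_chain_matrix <- function(geometry, gamma_deg) {
  rot_y(gamma_deg) %*% rot_z(geometry$chi_deg) %*%
    rot_x(geometry$epsilon_deg) %*% t(rot_x(geometry$delta_deg))
}

# A fast patient-4-like spec (short sweeps keep recordings small where the
# full 15 s profile is not itself under test).
quick_spec <- function(..., noise = noise_spec(0, 0), seed = 7) {
  virtual_patient_spec(..., noise = noise, seed = seed)
}

patient4_truth <- c(max_force_N = 186.9, min_force_N = 93.0,
                    gamma_at_min_deg = 15.7, force_at_90_N = 155.1)

# strip class and attributes from a force_vector
fv <- function(f) as.numeric(unclass(f))
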