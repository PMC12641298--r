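## Shared fixtures, built once per test run. Everything is generated in code;
## the short squat (3 reps) keeps most tests fast while the full-protocol
## profiles are reserved for the end-to-end acceptance checks.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = fixture_env)) assign(name, build(), envir = fixture_env)
  get(name, envir = fixture_env)
}

short_squat_profile <- function() {
  movement_profile("squat", reps_per_set = 3)
}

fix_truth_short <- function() {
  fixture("truth_short", function() make_trajectory(short_squat_profile(), rate = 250))
}

fix_rec_noise_free <- function() {
  fixture("rec_noise_free", function()
    simulate_marg(fix_truth_short(), noise = noise_spec_none(), clock_offset = 0.8))
}

fix_ref_offset <- function() {
  fixture("ref_offset", function()
    simulate_omc(fix_truth_short(), frame_yaw_offset = 37))
}

fix_mag_cal_noise_free <- function() {
  fixture("mag_cal_noise_free", function()
    fit_magnetometer_ellipsoid(
      to_right_handed(simulate_calibration_recording(noise = noise_spec_none()))))
}

## uniformly random unit quaternions
random_quats <- function(n, seed = 1) {
  set.seed(seed)
  quat_normalize(matrix(rnorm(4 * n), ncol = 4))
}

## points on a unit sphere
random_sphere_points <- function(n, seed = 1) {
  set.seed(seed)
  p <- matrix(rnorm(3 * n), ncol = 3)
  p / sqrt(rowSums(p^2))
}

expect_angle_equal <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(wrap_deg(a - b))), tol)
}
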