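test_that("already-calibrated data yields an identity calibration", {
  pts <- 0.5 * random_sphere_points(300, seed = 3)   # field-magnitude sphere
  cal <- fit_magnetometer_ellipsoid(pts)
  expect_equal(cal$hard_iron, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(cal$soft_iron_inv, diag(3), tolerance = 1e-9)
  expect_equal(cal$field_magnitude, 0.5, tolerance = 1e-9)
  expect_lt(cal$norm_cv, 1e-12)
})

test_that("noise-free iron distortion is inverted to numerical precision", {
  S <- diag(c(1.2, 1.0, 0.8))
  h <- c(0.30, -0.10, 0.05)
  raw <- random_sphere_points(400, seed = 5) %*% S +
    matrix(h, 400, 3, byrow = TRUE)
  cal <- fit_magnetometer_ellipsoid(raw)
  expect_equal(cal$hard_iron, h, tolerance = 1e-6)
  ## axis ratios of the inverse map recover 1/diag(S) up to the det-1 scale
  ev <- sort(eigen(cal$soft_iron_inv, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(ev / ev[2], sort(1 / c(1.2, 1, 0.8)) / 1, tolerance = 1e-6)
  expect_equal(det(cal$soft_iron_inv), 1, tolerance = 1e-9)
  ## calibrated data is spherical again
  expect_lt(cal$norm_cv, 1e-9)
})

test_that("hard iron is recovered within 1% of radius under 1% noise", {
  S <- diag(c(1.2, 1.0, 0.8))
  h <- c(0.30, -0.10, 0.05)
  worst <- 0
  for (seed in 1:20) {
    set.seed(seed)
    raw <- random_sphere_points(500, seed = seed) %*% S +
      matrix(h, 500, 3, byrow = TRUE) + matrix(rnorm(1500, 0, 0.01), 500, 3)
    cal <- fit_magnetometer_ellipsoid(raw)
    worst <- max(worst, sqrt(sum((cal$hard_iron - h)^2)))
  }
  expect_lt(worst, 0.01)   # 1% of the unit radius
})

test_that("degenerate sample clouds raise an explicit geometry error", {
  flat <- cbind(random_sphere_points(100, seed = 2)[, 1:2], 0.2)  # coplanar
  expect_error(fit_magnetometer_ellipsoid(flat), "degenerate")
  expect_error(fit_magnetometer_ellipsoid(matrix(rnorm(9), 3, 3)), "at least 10")
  ## an arc of orientations (single exercise set) is also insufficient
  arc <- t(sapply(seq(0, 40, length.out = 120), function(a)
    drop(quat_rotate(quat_conjugate(quat_from_axis_angle(c(1, 0, 0), a)),
                     lab_frame()$field))))
  expect_error(fit_magnetometer_ellipsoid(arc), "degenerate")
})

test_that("calibration application matches its definition and fixed points", {
  cal <- structure(list(soft_iron_inv = diag(3), hard_iron = c(0, 0, 0),
                        field_magnitude = 1, norm_cv = 0),
                   class = "mag_calibration")
  pts <- random_sphere_points(50, seed = 9)
  expect_equal(apply_mag_calibration(pts, cal), pts, ignore_attr = TRUE)
  cal$hard_iron <- c(0.2, 0.1, -0.3)
  expect_equal(drop(apply_mag_calibration(rbind(cal$hard_iron), cal)), c(0, 0, 0),
               ignore_attr = TRUE)
})

test_that("calibration is idempotent and rotation-equivariant", {
  S <- matrix(c(1.1, 0.05, 0, 0.05, 0.95, 0.02, 0, 0.02, 0.85), 3, 3)
  h <- c(0.2, -0.05, 0.1)
  raw <- random_sphere_points(400, seed = 11) %*% S + matrix(h, 400, 3, byrow = TRUE)
  cal <- fit_magnetometer_ellipsoid(raw)
  ## refitting the calibrated output finds (numerically) nothing left to fix
  cal2 <- fit_magnetometer_ellipsoid(apply_mag_calibration(raw, cal))
  expect_lt(max(abs(cal2$hard_iron)), 1e-6)
  expect_equal(cal2$soft_iron_inv, diag(3), tolerance = 1e-6)
  ## rotating the cloud rotates the hard iron and conjugates the soft iron
  R <- quat_to_dcm(quat_from_axis_angle(c(1, 2, 3), 55))
  cal_rot <- fit_magnetometer_ellipsoid(raw %*% t(R))
  expect_equal(cal_rot$hard_iron, drop(R %*% cal$hard_iron), tolerance = 1e-6)
  expect_equal(cal_rot$soft_iron_inv, R %*% cal$soft_iron_inv %*% t(R),
               tolerance = 1e-6)
})

test_that("static gyro bias is recovered exactly without noise", {
  p <- movement_profile("custom", static_lead = 5, static_tail = 0,
                        reps_per_set = 1, rep_period = 0.5)
  gt <- make_trajectory(p, rate = 250)
  ns <- noise_spec_none()
  ns$gyro_bias <- c(1, 0, 0)
  rec <- simulate_marg(gt, spec = sensor_spec(handedness = "right"), noise = ns)
  cal <- estimate_gyro_bias(rec, window = c(0.5, 4.5))
  expect_equal(cal$bias, c(x = 1, y = 0, z = 0))
  corrected <- apply_gyro_calibration(rec, cal)
  lead <- corrected$gyro$t_s < 4.5
  expect_lt(max(abs(as.matrix(corrected$gyro[lead, c("x", "y", "z")]))), 1e-12)
})

test_that("noisy bias estimate is within the standard-error bound", {
  p <- movement_profile("custom", static_lead = 5, static_tail = 0,
                        reps_per_set = 1, rep_period = 0.5)
  gt <- make_trajectory(p, rate = 250)
  sigma <- 0.1
  n_win <- 5 * 52
  bound <- 3 * sigma / sqrt(n_win)
  fails <- 0
  for (seed in 1:10) {
    ns <- noise_spec(accel_sigma = 0, gyro_sigma = sigma, mag_sigma = 0,
                     gyro_bias = c(1, 0, 0), hard_iron = c(0, 0, 0),
                     soft_iron = diag(3), seed = seed)
    rec <- simulate_marg(gt, spec = sensor_spec(handedness = "right"), noise = ns)
    cal <- estimate_gyro_bias(rec, window = c(0, 5), gate_dps = 3)
    if (any(abs(cal$bias - c(1, 0, 0)) > bound)) fails <- fails + 1
  }
  ## 3-sigma bound per axis: a rare single failure is statistically allowed
  expect_lte(fails, 1)
})

test_that("a moving window fails the static gate with a named axis", {
  gt <- fix_truth_short()
  rec <- simulate_marg(gt, spec = sensor_spec(handedness = "right"),
                       noise = noise_spec_none())
  expect_error(estimate_gyro_bias(rec, window = c(6, 9)), "static gate.*axis RMS|axis.*RMS",
               ignore.case = TRUE)
  expect_error(estimate_gyro_bias(rec, window = c(1, 1.5)), "at least 1 second")
})

test_that("auto-detected window lands in a static segment", {
  gt <- fix_truth_short()
  ns <- noise_spec(seed = 4)
  rec <- simulate_marg(gt, noise = ns, clock_offset = 0.8)
  cal <- estimate_gyro_bias(to_right_handed(rec))
  ## statics are [0.8, 5.8] and [14.8, 19.8] on the sensor clock
  in_lead <- cal$static_window[1] >= 0.8 && cal$static_window[2] <= 5.9
  in_tail <- cal$static_window[1] >= 14.7 && cal$static_window[2] <= 19.9
  expect_true(in_lead || in_tail)
  ## bias is injected in the physical frame before the handedness flip, so the
  ## round trip through to_right_handed() restores its sign
  expect_equal(unname(cal$bias), c(1, 1, 1), tolerance = 0.2)
})
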