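test_that("handedness transform is a guarded involution", {
  rec <- fix_rec_noise_free()
  expect_identical(rec$handedness, "left")
  rh <- to_right_handed(rec)
  expect_identical(rh$handedness, "right")
  expect_error(to_right_handed(rh), "already right-handed")
  ## manual inverse restores the original bit-for-bit
  back <- rh
  for (comp in c("accel", "gyro", "mag")) back[[comp]]$y <- -back[[comp]]$y
  back$handedness <- "left"
  expect_identical(back, rec)
})

test_that("right-handed streams satisfy the rotation cross-product convention", {
  ## during a pure positive pitch rotation (about sensor X), the gravity
  ## reaction swings from +z toward +y in the sensor frame under the
  ## right-hand rule: gyro x > 0 while accel y grows
  p <- movement_profile("custom", amplitude = c(roll = 0, pitch = 40, yaw = 0),
                        static_lead = 1, static_tail = 0, reps_per_set = 1,
                        rep_period = 2)
  gt <- make_trajectory(p, rate = 250)
  rh <- to_right_handed(simulate_marg(gt, noise = noise_spec_none(
    start_offsets = c(accel = 0, gyro = 0, mag = 0))))
  rising <- rh$gyro$t_s > 1.1 & rh$gyro$t_s < 1.8
  expect_true(all(rh$gyro$x[rising] > 0))
  acc_rising <- rh$accel$t_s > 1.2 & rh$accel$t_s < 1.9
  expect_true(all(rh$accel$y[acc_rising] > 0))
})

test_that("cropping takes the latest start and earliest end", {
  mk <- function(t0, t1, rate) {
    t <- seq(t0, t1, by = 1 / rate)
    tibble::tibble(t_s = t, x = 0, y = 0, z = 1)
  }
  rec <- margsense:::new_marg_recording(mk(0, 10, 52), mk(0.12, 10, 52),
                                        mk(0.31, 10.5, 100))
  cropped <- crop_common_origin(rec)
  expect_equal(attr(cropped, "origin"), 0.31)
  for (comp in c("accel", "gyro", "mag")) {
    expect_gte(min(cropped[[comp]]$t_s), 0.31)
    expect_lte(max(cropped[[comp]]$t_s), 10)
  }
  ## equal spans pass through unchanged
  rec2 <- margsense:::new_marg_recording(mk(0, 5, 52), mk(0, 5, 52), mk(0, 5, 100))
  cropped2 <- crop_common_origin(rec2)
  expect_equal(cropped2$accel, rec2$accel)
  ## disjoint spans error
  rec3 <- margsense:::new_marg_recording(mk(0, 1, 52), mk(2, 3, 52), mk(0, 1, 100))
  expect_error(crop_common_origin(rec3), "overlap")
})

test_that("resampling preserves constants, sinusoids and wrapped angles", {
  t100 <- seq(0, 10, by = 0.01)
  const <- tibble::tibble(t_s = t100, x = 2, y = -1, z = 0.5)
  rc <- resample(const, 52)
  expect_equal(unique(rc$x), 2)
  expect_equal(diff(rc$t_s), rep(1 / 52, nrow(rc) - 1L), tolerance = 1e-12)

  sine <- tibble::tibble(t_s = t100, x = sin(2 * pi * t100), y = 0, z = 0)
  rs <- resample(sine, 52)
  expect_lt(max(abs(rs$x - sin(2 * pi * rs$t_s))), 0.001)  # 0.1% of amplitude

  ## a yaw ramp crossing +180 must not spike after resampling
  yaw <- wrap_deg(30 * t100)
  traj <- new_euler_trajectory(
    tibble::tibble(t_s = t100, roll_deg = 0, pitch_deg = 0, yaw_deg = yaw),
    rate = 100, frame = "lab")
  rt <- resample(traj, 52)
  expect_lt(max(abs(wrap_deg(rt$yaw_deg - wrap_deg(30 * rt$t_s)))), 0.01)
  expect_lt(max(abs(diff(unwrap_deg(rt$yaw_deg)))), 1)   # no 360-degree jumps
})

test_that("synchronization recovers constructed lags to sub-sample precision", {
  ref <- fix_ref_offset()
  expect_equal(synchronize(ref, ref)$lag, 0, tolerance = 1e-9)

  ## shift by exactly 17 samples at 250 Hz
  shifted <- ref
  shifted$t_s <- shifted$t_s + 17 / 250
  s <- synchronize(shifted, ref)
  expect_equal(s$lag * 250, 17, tolerance = 0.1)
  expect_identical(s$channel, "pitch_deg")   # squat: pitch carries the feature

  ## fractional lags too
  shifted$t_s <- ref$t_s + 0.1234
  s2 <- synchronize(shifted, ref)
  expect_equal(s2$lag, 0.1234, tolerance = 0.1 / 250)

  ## applying the sync puts the series back on the reference clock
  expect_equal(apply_sync(shifted, s2)$t_s[1], ref$t_s[1], tolerance = 0.1 / 250)
})

test_that("flat series cannot be synchronized", {
  flat <- new_euler_trajectory(
    tibble::tibble(t_s = seq(0, 10, by = 1 / 250), roll_deg = 1, pitch_deg = 2,
                   yaw_deg = 3), rate = 250, frame = "lab")
  expect_error(synchronize(flat, flat), "variance floor")
})

test_that("heading offset estimation uses circular means", {
  ref <- fix_ref_offset()
  expect_equal(estimate_heading_offset(ref, ref, c(0.5, 4.5))$delta_psi, 0,
               tolerance = 1e-9)

  sensor <- simulate_omc(fix_truth_short(), frame_yaw_offset = 0)
  h <- estimate_heading_offset(sensor, ref, c(0.5, 4.5))
  expect_equal(h$delta_psi, 37, tolerance = 1e-6)

  ## straddling the +/-180 seam: sensor -179, reference +179 is a -2 offset...
  mk_static <- function(yaw) new_euler_trajectory(
    tibble::tibble(t_s = seq(0, 5, by = 1 / 250), roll_deg = 0, pitch_deg = 0,
                   yaw_deg = yaw), rate = 250, frame = "lab")
  h2 <- estimate_heading_offset(mk_static(-179), mk_static(179), c(0.5, 4.5))
  expect_equal(h2$delta_psi, -2, tolerance = 1e-9)
  ## ... never +358
  expect_lte(abs(h2$delta_psi), 180)
  expect_error(estimate_heading_offset(ref, ref, c(1, 1.2)), "0.5")
})

test_that("heading correction rotates yaw only for level static poses", {
  p <- movement_profile("custom", static_lead = 2, static_tail = 0,
                        reps_per_set = 1, rep_period = 0.5,
                        base_pose = c(20, 30, 10))    # tilted but |roll| < 80
  traj <- truth_to_euler(make_trajectory(p, rate = 100))
  corr <- structure(list(delta_psi = 37, window = c(0, 2)),
                    class = "heading_correction")
  out <- apply_heading_correction(traj, corr)
  ## identity when delta is zero
  corr0 <- structure(list(delta_psi = 0, window = c(0, 2)),
                     class = "heading_correction")
  expect_equal(apply_heading_correction(traj, corr0), traj, tolerance = 1e-12)
  ## the corrected trajectory is the frame-rotated orientation, DCMs stay proper
  q_in <- euler_xyz_to_quat(traj$roll_deg[1], traj$pitch_deg[1], traj$yaw_deg[1])
  q_out <- euler_xyz_to_quat(out$roll_deg[1], out$pitch_deg[1], out$yaw_deg[1])
  q_expect <- quat_multiply(quat_from_axis_angle(c(0, 0, 1), 37), q_in)
  expect_lt(quat_angle_deg(q_out, q_expect), 1e-9)
  expect_equal(det(quat_to_dcm(q_out)), 1, tolerance = 1e-9)
})

test_that("estimate-then-apply closes the heading loop", {
  ref <- fix_ref_offset()
  sensor <- simulate_omc(fix_truth_short(), frame_yaw_offset = 0)
  h <- estimate_heading_offset(sensor, ref, c(0.5, 4.5))
  corrected <- apply_heading_correction(sensor, h)
  resid <- estimate_heading_offset(corrected, ref, c(0.5, 4.5))
  expect_lt(abs(resid$delta_psi), 0.1)
})

test_that("heading correction leaves static pitch/roll untouched away from the singularity", {
  for (base in list(c(0, 0, 0), c(40, 30, -20), c(70, -45, 100))) {
    p <- movement_profile("custom", static_lead = 1, static_tail = 0,
                          reps_per_set = 1, rep_period = 0.5, base_pose = base)
    traj <- truth_to_euler(make_trajectory(p, rate = 52))
    corr <- structure(list(delta_psi = 53, window = c(0, 1)),
                      class = "heading_correction")
    out <- apply_heading_correction(traj, corr)
    expect_lt(max(abs(out$roll_deg - traj$roll_deg)), 1e-6)
    expect_lt(max(abs(out$pitch_deg - traj$pitch_deg)), 1e-6)
    expect_angle_equal(out$yaw_deg, traj$yaw_deg + 53, tol = 1e-6)
  }
})

test_that("baselining zeroes the static window and respects wrapping", {
  p <- movement_profile("custom", static_lead = 2, static_tail = 0,
                        reps_per_set = 1, rep_period = 1,
                        base_pose = c(0, 12, 179))
  traj <- truth_to_euler(make_trajectory(p, rate = 100))
  out <- baseline_to_zero(traj, c(0, 2))
  sel <- out$t_s <= 2
  expect_lt(max(abs(out$pitch_deg[sel])), 1e-9)
  expect_lt(max(abs(out$yaw_deg[sel])), 1e-9)   # no wrap artefact at 179 deg
  ## already-baselined series is unchanged
  expect_equal(baseline_to_zero(out, c(0, 2)), out, tolerance = 1e-9)
  expect_error(baseline_to_zero(traj, c(100, 101)), "outside")
})

test_that("merged components share one grid with no mutual time shift", {
  rec <- to_right_handed(fix_rec_noise_free())
  m <- merge_components(rec)
  expect_equal(diff(m$t_s), rep(1 / 52, nrow(m) - 1L), tolerance = 1e-12)
  gt <- fix_truth_short()
  om <- margsense:::quat_angular_velocity(gt$t_s, as.matrix(gt[, c("qw", "qx", "qy", "qz")]))
  om_deg <- margsense:::rad2deg(om)
  truth_at <- vapply(1:3, function(j)
    stats::approx(gt$t_s + 0.8, om_deg[, j], xout = m$t_s)$y, numeric(nrow(m)))
  ## bounded by double linear interpolation of the 52 Hz gyro onto the shifted
  ## grid: ~0.3% of the 42 deg/s peak rate
  expect_lt(max(abs(as.matrix(m[, c("gx", "gy", "gz")]) - truth_at)), 0.2)
})
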