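#' Sensor, noise and lab-frame specifications
#'
#' `sensor_spec()` captures the device datasheet: an accelerometer (+/- 8 g,
#' 52 Hz), gyroscope (+/- 2000 deg/s, 52 Hz) and magnetometer (100 Hz), logging
#' in a left-handed frame. `noise_spec()` captures the error sources the
#' calibration stage later removes; its defaults are the study conditions used
#' throughout the package's recovery checks: gyro bias 1 deg/s per axis, accel
#' noise 0.02 g, hard-iron offset (0.3, 0, 0) gauss and soft-iron distortion
#' diag(1.2, 1.0, 0.8), plus per-component start-time offsets reflecting the
#' components' different initialization durations. `noise_spec_none()` keeps
#' the start offsets but zeroes every stochastic term. `lab_frame()` fixes the
#' lab conventions: gravity (0, 0, -1) g and a geomagnetic field of 0.5 gauss
#' with a 60-degree downward inclination, lying in the x-z plane so lab +x is
#' magnetic north.
#'
#' @param accel_range,gyro_range full-scale ranges (g, deg/s).
#' @param accel_rate,gyro_rate,mag_rate sampling rates in Hz.
#' @param handedness `"left"` (device native) or `"right"`.
#' @param accel_sigma,gyro_sigma,mag_sigma Gaussian noise SDs (g, deg/s, gauss).
#' @param gyro_bias length-3 constant gyro bias, deg/s.
#' @param hard_iron length-3 additive magnetometer offset, gauss.
#' @param soft_iron 3 x 3 symmetric positive-definite distortion matrix.
#' @param start_offsets named numeric: per-component start times (s) in the
#'   sensor's own clock.
#' @param seed integer RNG seed for the simulated noise.
#' @param gravity_g gravity magnitude in g.
#' @param field_gauss geomagnetic field magnitude in gauss.
#' @param dip_deg downward field inclination in degrees.
#' @return spec lists of class `sensor_spec`, `noise_spec`, `lab_frame`.
#' @name specs
NULL

#' @rdname specs
#' @export
sensor_spec <- function(accel_range = 8, accel_rate = 52,
                        gyro_range = 2000, gyro_rate = 52,
                        mag_rate = 100, handedness = c("left", "right")) {
  handedness <- match.arg(handedness)
  for (v in c("accel_range", "accel_rate", "gyro_range", "gyro_rate", "mag_rate")) {
    stopifnot_scalar_number(get(v), v, min = 1e-9)
  }
  structure(list(accel_range = accel_range, accel_rate = accel_rate,
                 gyro_range = gyro_range, gyro_rate = gyro_rate,
                 mag_rate = mag_rate, handedness = handedness),
            class = "sensor_spec")
}

#' @rdname specs
#' @export
noise_spec <- function(accel_sigma = 0.02, gyro_sigma = 0.5,
                       gyro_bias = c(1, 1, 1), mag_sigma = 0.005,
                       hard_iron = c(0.3, 0, 0),
                       soft_iron = diag(c(1.2, 1.0, 0.8)),
                       start_offsets = c(accel = 0, gyro = 0.12, mag = 0.31),
                       seed = NULL) {
  if (any(c(accel_sigma, gyro_sigma, mag_sigma) < 0)) abort("noise sigmas must be >= 0")
  ev <- eigen(soft_iron, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) abort("`soft_iron` must be positive definite")
  start_offsets <- start_offsets[c("accel", "gyro", "mag")]
  if (anyNA(start_offsets)) abort("`start_offsets` needs named entries accel, gyro, mag")
  structure(list(accel_sigma = accel_sigma, gyro_sigma = gyro_sigma,
                 gyro_bias = rep_len(gyro_bias, 3L), mag_sigma = mag_sigma,
                 hard_iron = rep_len(hard_iron, 3L), soft_iron = soft_iron,
                 start_offsets = start_offsets, seed = seed),
            class = "noise_spec")
}

#' @rdname specs
#' @export
noise_spec_none <- function(start_offsets = c(accel = 0, gyro = 0.12, mag = 0.31)) {
  noise_spec(accel_sigma = 0, gyro_sigma = 0, gyro_bias = c(0, 0, 0),
             mag_sigma = 0, hard_iron = c(0, 0, 0), soft_iron = diag(3),
             start_offsets = start_offsets)
}

#' @rdname specs
#' @export
lab_frame <- function(gravity_g = 1, field_gauss = 0.5, dip_deg = 60) {
  structure(list(
    gravity = c(0, 0, -gravity_g),
    ## accelerometer measures specific force, i.e. the reaction: +z when level
    gravity_reaction = c(0, 0, gravity_g),
    field = field_gauss * c(cos(deg2rad(dip_deg)), 0, -sin(deg2rad(dip_deg))),
    field_gauss = field_gauss, dip_deg = dip_deg
  ), class = "lab_frame")
}

flip_axis_column <- function(m, axis = LEFT_HANDED_FLIP_AXIS) {
  m[, axis] <- -m[, axis]
  m
}

#' Forward-model the MARG sensor streams from a ground-truth trajectory
#'
#' Samples each component at its own rate and start offset, in the sensor's
#' own clock (`t_sensor = t_truth + clock_offset`): the accelerometer reads
#' the gravity reaction rotated into the sensor frame (plus noise), the
#' gyroscope reads the true body angular velocity plus a constant bias and
#' noise, and the magnetometer reads `soft_iron %*% field_sensor + hard_iron`
#' plus noise. Samples are clipped to the component ranges (silently, but
#' counted in the recording's `clipped` field). When the spec's handedness is
#' left, the y-axis of all three components is negated -- the single
#' documented convention shared with [to_right_handed()].
#'
#' Linear acceleration defaults to zero (orientation-only trajectories); pass
#' `linear_accel` as a function of truth time returning an n x 3 matrix of
#' lab-frame accelerations in g to emulate violations of the
#' static-accelerometer assumption.
#'
#' @param truth a `ground_truth` trajectory from [make_trajectory()].
#' @param spec a [sensor_spec()].
#' @param noise a [noise_spec()].
#' @param placement placement label (C, LW, RW, LT, RT, LA, RA).
#' @param clock_offset sensor clock minus truth clock, seconds. Emulates the
#'   independent triggering of the two systems: the cross-correlation
#'   synchronizer must recover it.
#' @param lab a [lab_frame()].
#' @param linear_accel optional `function(t)` -> n x 3 lab-frame linear
#'   acceleration in g.
#' @return a `marg_recording`.
#' @examples
#' gt <- make_trajectory(movement_profile("squat"), rate = 250)
#' rec <- simulate_marg(gt, noise = noise_spec_none())
#' @export
simulate_marg <- function(truth, spec = sensor_spec(), noise = noise_spec(),
                          placement = "C", clock_offset = 0,
                          lab = lab_frame(), linear_accel = NULL) {
  q_truth <- ground_truth_quat(truth)
  t_truth <- truth$t_s
  t_end <- t_truth[length(t_truth)]
  if (!is.null(noise$seed)) set.seed(as.integer(noise$seed))

  sample_times <- function(offset, rate) {
    if (offset > t_end) abort("component start offset beyond trajectory end")
    offset + (seq_len(floor((t_end - offset) * rate) + 1L) - 1L) / rate
  }
  rotate_into_sensor <- function(q, v_lab) {
    ## v expressed in sensor coords: R^T v = q* (0, v) q
    quat_rotate(quat_conjugate(q), v_lab)
  }
  clipped <- c(accel = 0L, gyro = 0L, mag = 0L)
  clip <- function(m, range, comp) {
    n_out <- sum(abs(m) > range)
    clipped[comp] <<- as.integer(n_out)
    pmin(pmax(m, -range), range)
  }

  ## accelerometer
  ta <- sample_times(noise$start_offsets["accel"], spec$accel_rate)
  qa <- quat_interp(t_truth, q_truth, ta)
  acc <- rotate_into_sensor(qa, matrix(lab$gravity_reaction, nrow = length(ta),
                                       ncol = 3, byrow = TRUE))
  if (!is.null(linear_accel)) {
    la <- linear_accel(ta)
    acc <- acc + t(vapply(seq_along(ta), function(i)
      quat_rotate(quat_conjugate(qa[i, , drop = FALSE]), la[i, ])[1, ],
      numeric(3)))
  }
  if (noise$accel_sigma > 0) acc <- acc + matrix(rnorm(length(acc), 0, noise$accel_sigma), ncol = 3)
  acc <- clip(acc, spec$accel_range, "accel")

  ## gyroscope: true body rates from the quaternion derivative
  omega_truth <- rad2deg(quat_angular_velocity(t_truth, q_truth))
  tg <- sample_times(noise$start_offsets["gyro"], spec$gyro_rate)
  gyr <- vapply(1:3, function(j) approx(t_truth, omega_truth[, j], xout = tg, rule = 2)$y,
                numeric(length(tg)))
  gyr <- matrix(gyr, ncol = 3) + matrix(noise$gyro_bias, nrow = length(tg), ncol = 3, byrow = TRUE)
  if (noise$gyro_sigma > 0) gyr <- gyr + matrix(rnorm(length(gyr), 0, noise$gyro_sigma), ncol = 3)
  gyr <- clip(gyr, spec$gyro_range, "gyro")

  ## magnetometer with iron distortion
  tm <- sample_times(noise$start_offsets["mag"], spec$mag_rate)
  qm <- quat_interp(t_truth, q_truth, tm)
  fld <- rotate_into_sensor(qm, matrix(lab$field, nrow = length(tm), ncol = 3, byrow = TRUE))
  mag <- fld %*% t(noise$soft_iron) +
    matrix(noise$hard_iron, nrow = length(tm), ncol = 3, byrow = TRUE)
  if (noise$mag_sigma > 0) mag <- mag + matrix(rnorm(length(mag), 0, noise$mag_sigma), ncol = 3)

  comps <- list(
    accel = tibble(t_s = ta + clock_offset, x = acc[, 1], y = acc[, 2], z = acc[, 3]),
    gyro  = tibble(t_s = tg + clock_offset, x = gyr[, 1], y = gyr[, 2], z = gyr[, 3]),
    mag   = tibble(t_s = tm + clock_offset, x = mag[, 1], y = mag[, 2], z = mag[, 3])
  )
  if (spec$handedness == "left") {
    comps <- lapply(comps, function(d) { d[[LEFT_HANDED_FLIP_AXIS]] <- -d[[LEFT_HANDED_FLIP_AXIS]]; d })
  }
  new_marg_recording(comps$accel, comps$gyro, comps$mag,
                     placement = placement, handedness = spec$handedness,
                     rates = c(accel = spec$accel_rate, gyro = spec$gyro_rate,
                               mag = spec$mag_rate),
                     clipped = clipped, seed = noise$seed)
}

#' Simulate a magnetometer-calibration recording
#'
#' Forward-models a [make_tumble_trajectory()] maneuver with the same sensor
#' and noise specification as the exercise recordings, giving the
#' well-distributed magnetometer cloud that [fit_magnetometer_ellipsoid()]
#' needs. The fitted calibration is then reused for the session's exercise
#' sets via `process_recording(mag_cal = )`.
#'
#' @inheritParams simulate_marg
#' @param duration tumble duration in seconds.
#' @return a `marg_recording`.
#' @export
simulate_calibration_recording <- function(spec = sensor_spec(),
                                           noise = noise_spec(),
                                           duration = 20, placement = "C",
                                           lab = lab_frame()) {
  truth <- make_tumble_trajectory(duration = duration)
  simulate_marg(truth, spec = spec, noise = noise, placement = placement,
                lab = lab)
}

#' Forward-model the reference optical-motion-capture orientation series
#'
#' Re-expresses the ground truth in a reference lab frame rotated by
#' `frame_yaw_offset` about the vertical axis -- the constant heading
#' misalignment between the sensor's geomagnetic global frame and the capture
#' system's calibrated lab frame -- samples it on a uniform 250 Hz grid, and
#' optionally adds Gaussian angle noise.
#'
#' @param truth a `ground_truth` trajectory.
#' @param frame_yaw_offset degrees, |offset| <= 180.
#' @param noise_sigma per-angle Gaussian noise SD in degrees.
#' @param seed integer RNG seed.
#' @param rate output rate in Hz (default 250).
#' @param segment segment label carried in the output.
#' @return an `euler_trajectory` with frame `"reference-lab"`.
#' @examples
#' gt <- make_trajectory(movement_profile("squat"), rate = 250)
#' omc <- simulate_omc(gt, frame_yaw_offset = 37)
#' @export
simulate_omc <- function(truth, frame_yaw_offset = 0, noise_sigma = 0,
                         seed = NULL, rate = 250, segment = "C") {
  if (abs(frame_yaw_offset) > 180) abort("|frame_yaw_offset| must be <= 180")
  t_truth <- truth$t_s
  t_end <- t_truth[length(t_truth)]
  t_out <- (seq_len(floor(t_end * rate) + 1L) - 1L) / rate
  q <- quat_interp(t_truth, ground_truth_quat(truth), t_out)
  q_off <- quat_from_axis_angle(c(0, 0, 1), frame_yaw_offset)
  e <- quat_to_euler_xyz(quat_multiply(q_off, q))
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    e$roll_deg <- e$roll_deg + rnorm(nrow(e), 0, noise_sigma)
    e$pitch_deg <- e$pitch_deg + rnorm(nrow(e), 0, noise_sigma)
    e$yaw_deg <- e$yaw_deg + rnorm(nrow(e), 0, noise_sigma)
  }
  out <- new_euler_trajectory(
    tibble(t_s = t_out, roll_deg = e$roll_deg, pitch_deg = e$pitch_deg,
           yaw_deg = e$yaw_deg),
    rate = rate, frame = "reference-lab"
  )
  attr(out, "segment") <- segment
  out
}
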