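#' Filter configuration
#'
#' @param beta gradient-descent gain (dimensionless, >= 0). The default 0.1
#'   is the filter's conventional default and the value used throughout the
#'   package's validation; larger values trust the accelerometer/magnetometer
#'   correction more, smaller values trust gyroscope integration more.
#' @param sample_period seconds between fused samples (default 1/52).
#' @param q0 initial orientation: `"from-first-sample"` (analytic TRIAD-style
#'   orientation from the first accelerometer + magnetometer pair; the
#'   protocol starts every set with a static pose, so this is accurate from
#'   sample zero) or a unit quaternion.
#' @return a `filter_config` list.
#' @export
filter_config <- function(beta = 0.1, sample_period = 1 / 52,
                          q0 = "from-first-sample") {
  if (beta < 0) abort("`beta` must be >= 0")
  stopifnot_scalar_number(sample_period, "sample_period", min = 1e-9)
  if (!identical(q0, "from-first-sample")) {
    q0 <- quat_normalize(as_quat_matrix(q0))
  }
  structure(list(beta = beta, sample_period = sample_period, q0 = q0),
            class = "filter_config")
}

#' One step of the Madgwick gradient-descent MARG filter
#'
#' Advances a unit quaternion by one sample: the quaternion rate implied by
#' the gyroscope, corrected by `-beta` times the normalized gradient of the
#' combined gravity + geomagnetic-field objective, integrated over
#' `sample_period` and renormalized. The magnetic reference is decomposed
#' into horizontal and vertical components (`b = (bx, 0, bz)`) at every step,
#' so the magnetometer corrects heading only and cannot tilt the estimate.
#'
#' Accelerometer and magnetometer inputs are direction-normalized internally,
#' so their scales are irrelevant. A zero-norm accelerometer or magnetometer
#' sample skips the corrective term for that step (pure gyro propagation) and
#' is counted by the caller.
#'
#' @param q current unit quaternion (1 x 4 or length 4, scalar-first).
#' @param gyro body angular rates in rad/s (length 3).
#' @param accel accelerometer sample, any scale (length 3).
#' @param mag magnetometer sample, any scale (length 3).
#' @param cfg a [filter_config()].
#' @return the updated 1 x 4 unit quaternion.
#' @export
madgwick_update <- function(q, gyro, accel, mag, cfg = filter_config()) {
  q <- as_quat_matrix(q)
  q0 <- q[1, 1]; q1 <- q[1, 2]; q2 <- q[1, 3]; q3 <- q[1, 4]
  gx <- gyro[1]; gy <- gyro[2]; gz <- gyro[3]
  ## quaternion rate from gyroscope
  qDot0 <- 0.5 * (-q1 * gx - q2 * gy - q3 * gz)
  qDot1 <- 0.5 * (q0 * gx + q2 * gz - q3 * gy)
  qDot2 <- 0.5 * (q0 * gy - q1 * gz + q3 * gx)
  qDot3 <- 0.5 * (q0 * gz + q1 * gy - q2 * gx)

  an <- sqrt(sum(accel^2)); mn <- sqrt(sum(mag^2))
  if (cfg$beta > 0 && an > 0 && mn > 0) {
    ax <- accel[1] / an; ay <- accel[2] / an; az <- accel[3] / an
    mx <- mag[1] / mn; my <- mag[2] / mn; mz <- mag[3] / mn
    ## reference field direction in the lab frame, horizontal/vertical split
    h <- quat_rotate(q, c(mx, my, mz))
    bx <- sqrt(h[1]^2 + h[2]^2); bz <- h[3]
    ## objective function (gravity rows then field rows)
    f1 <- 2 * (q1 * q3 - q0 * q2) - ax
    f2 <- 2 * (q0 * q1 + q2 * q3) - ay
    f3 <- 2 * (0.5 - q1^2 - q2^2) - az
    f4 <- 2 * bx * (0.5 - q2^2 - q3^2) + 2 * bz * (q1 * q3 - q0 * q2) - mx
    f5 <- 2 * bx * (q1 * q2 - q0 * q3) + 2 * bz * (q0 * q1 + q2 * q3) - my
    f6 <- 2 * bx * (q0 * q2 + q1 * q3) + 2 * bz * (0.5 - q1^2 - q2^2) - mz
    ## gradient = J' f
    s0 <- -2 * q2 * f1 + 2 * q1 * f2 +
      (-2 * bz * q2) * f4 + (-2 * bx * q3 + 2 * bz * q1) * f5 + (2 * bx * q2) * f6
    s1 <- 2 * q3 * f1 + 2 * q0 * f2 - 4 * q1 * f3 +
      (2 * bz * q3) * f4 + (2 * bx * q2 + 2 * bz * q0) * f5 +
      (2 * bx * q3 - 4 * bz * q1) * f6
    s2 <- -2 * q0 * f1 + 2 * q3 * f2 - 4 * q2 * f3 +
      (-4 * bx * q2 - 2 * bz * q0) * f4 + (2 * bx * q1 + 2 * bz * q3) * f5 +
      (2 * bx * q0 - 4 * bz * q2) * f6
    s3 <- 2 * q1 * f1 + 2 * q2 * f2 +
      (-4 * bx * q3 + 2 * bz * q1) * f4 + (-2 * bx * q0 + 2 * bz * q2) * f5 +
      (2 * bx * q1) * f6
    sn <- sqrt(s0^2 + s1^2 + s2^2 + s3^2)
    if (sn > 0) {
      qDot0 <- qDot0 - cfg$beta * s0 / sn
      qDot1 <- qDot1 - cfg$beta * s1 / sn
      qDot2 <- qDot2 - cfg$beta * s2 / sn
      qDot3 <- qDot3 - cfg$beta * s3 / sn
    }
  }
  dt <- cfg$sample_period
  quat_normalize(quat(q0 + qDot0 * dt, q1 + qDot1 * dt,
                      q2 + qDot2 * dt, q3 + qDot3 * dt))
}

#' Analytic orientation from one accelerometer + magnetometer pair
#'
#' TRIAD-style static orientation: the accelerometer gives the lab vertical
#' in sensor coordinates, the magnetometer's horizontal component gives
#' magnetic north. Used to initialize the filter from the protocol's static
#' lead pose and as an independent static-orientation oracle.
#'
#' @param accel,mag length-3 samples (any scale; accel must not be zero or
#'   parallel to mag).
#' @return a 1 x 4 unit quaternion (sensor relative to lab).
#' @export
orientation_from_accel_mag <- function(accel, mag) {
  up <- accel / sqrt(sum(accel^2))
  mh <- mag - sum(mag * up) * up
  nh <- sqrt(sum(mh^2))
  if (nh < 1e-12) abort("magnetometer parallel to gravity: heading unobservable")
  north <- mh / nh
  east <- c(up[2] * north[3] - up[3] * north[2],
            up[3] * north[1] - up[1] * north[3],
            up[1] * north[2] - up[2] * north[1])  # y = z x x
  R <- rbind(north, east, up)                      # rows: lab axes in sensor coords
  dimnames(R) <- NULL
  dcm_to_quat(R)
}

#' Run the orientation filter over a merged recording
#'
#' Applies [madgwick_update()] across a merged component stream (all three
#' components on a common uniform grid and temporal origin; see
#' [merge_components()]). Gyroscope input is converted from deg/s to rad/s
#' internally. The first quaternion comes from the `q0` policy of the config.
#'
#' @param merged a tibble from [merge_components()] with columns
#'   `t_s, ax, ay, az, gx, gy, gz, mx, my, mz`.
#' @param cfg a [filter_config()]; its `sample_period` is overridden by the
#'   merged stream's grid spacing.
#' @return a `quat_trajectory` tibble (`t_s, qw, qx, qy, qz`) with attributes
#'   `rate` and `skipped` (count of steps whose corrective term was skipped
#'   because of a zero-norm accel or mag sample).
#' @export
run_filter <- function(merged, cfg = filter_config()) {
  need <- c("t_s", "ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")
  if (!all(need %in% names(merged))) {
    abort("`merged` must come from merge_components() (common grid, all components)")
  }
  n <- nrow(merged)
  if (n < 2L) abort("merged stream too short to filter")
  dt <- merged$t_s[2L] - merged$t_s[1L]
  step_cfg <- cfg
  step_cfg$sample_period <- dt
  acc <- as.matrix(merged[, c("ax", "ay", "az")])
  gyr <- deg2rad(as.matrix(merged[, c("gx", "gy", "gz")]))
  mag <- as.matrix(merged[, c("mx", "my", "mz")])
  q <- matrix(0, n, 4L)
  q[1L, ] <- if (identical(cfg$q0, "from-first-sample")) {
    orientation_from_accel_mag(acc[1L, ], mag[1L, ])
  } else {
    cfg$q0
  }
  skipped <- 0L
  for (i in seq_len(n - 1L)) {
    if (sum(acc[i, ]^2) == 0 || sum(mag[i, ]^2) == 0) skipped <- skipped + 1L
    ## trapezoidal gyro rate over the step: avoids the half-sample delay of
    ## left-endpoint integration (~10 ms at 52 Hz, visible in synchronization)
    g_mid <- 0.5 * (gyr[i, ] + gyr[i + 1L, ])
    q[i + 1L, ] <- madgwick_update(q[i, , drop = FALSE], g_mid, acc[i, ],
                                   mag[i, ], step_cfg)
  }
  out <- tibble(t_s = merged$t_s, qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4])
  structure(out, rate = 1 / dt, skipped = skipped,
            class = c("quat_trajectory", class(out)))
}

#' Euler-angle view of a fused quaternion trajectory
#'
#' @param traj a `quat_trajectory` from [run_filter()].
#' @param frame frame tag for the result (default `"sensor-geomagnetic"`).
#' @return an `euler_trajectory`.
#' @export
quat_trajectory_to_euler <- function(traj, frame = "sensor-geomagnetic") {
  e <- quat_to_euler_xyz(as.matrix(traj[, c("qw", "qx", "qy", "qz")]))
  new_euler_trajectory(
    tibble(t_s = traj$t_s, roll_deg = e$roll_deg, pitch_deg = e$pitch_deg,
           yaw_deg = e$yaw_deg),
    rate = attr(traj, "rate"), frame = frame
  )
}
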