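#' Handedness transform
#'
#' The device logs in a left-handed sensor frame; the reference system and
#' all orientation math here are right-handed. The conversion negates one
#' documented axis (the y-axis, the single shared constant
#' `LEFT_HANDED_FLIP_AXIS`) on all three components. The transform is an
#' involution on the data, but the handedness flag makes accidental double
#' application an error.
#'
#' @param recording a left-handed `marg_recording`.
#' @return the recording with all y columns negated and handedness `"right"`.
#' @export
to_right_handed <- function(recording) {
  if (!inherits(recording, "marg_recording")) abort("`recording` must be a marg_recording")
  if (recording$handedness != "left") {
    abort("recording is already right-handed; refusing to flip an axis twice")
  }
  for (comp in c("accel", "gyro", "mag")) {
    recording[[comp]][[LEFT_HANDED_FLIP_AXIS]] <- -recording[[comp]][[LEFT_HANDED_FLIP_AXIS]]
  }
  recording$handedness <- "right"
  recording
}

#' Crop components to a common temporal origin
#'
#' The three components initialize at different times, so their streams start
#' asynchronously. Truncates all components to the intersection
#' `[max(starts), min(ends)]` of their spans.
#'
#' @param recording a `marg_recording`.
#' @return the cropped recording, with attribute `origin` = max of the
#'   component start times.
#' @export
crop_common_origin <- function(recording) {
  starts <- vapply(recording[c("accel", "gyro", "mag")], function(d) min(d$t_s), numeric(1))
  ends <- vapply(recording[c("accel", "gyro", "mag")], function(d) max(d$t_s), numeric(1))
  t0 <- max(starts); t1 <- min(ends)
  if (t0 >= t1) abort("component time spans do not overlap; cannot crop to a common origin")
  for (comp in c("accel", "gyro", "mag")) {
    d <- recording[[comp]]
    recording[[comp]] <- d[d$t_s >= t0 & d$t_s <= t1, ]
  }
  attr(recording, "origin") <- t0
  recording
}

#' Resample a vector stream or an Euler trajectory onto a uniform grid
#'
#' Linear interpolation onto a grid at `target_rate` starting at the input's
#' first timestamp. Vector streams (`t_s, x, y, z`) are interpolated
#' componentwise; Euler trajectories are interpolated on the unwrapped angle
#' representation and rewrapped, so series crossing the +/-180 seam do not
#' produce 360-degree spikes. The output grid never extends beyond the input
#' span (truncated, never extrapolated).
#'
#' @param series a tibble `t_s, x, y, z`, or an `euler_trajectory`.
#' @param target_rate output rate in Hz.
#' @return the resampled series, same type as the input.
#' @export
resample <- function(series, target_rate) {
  stopifnot_scalar_number(target_rate, "target_rate", min = 1e-9)
  t0 <- series$t_s[1L]
  t1 <- series$t_s[nrow(series)]
  t_out <- t0 + (seq_len(floor((t1 - t0) * target_rate) + 1L) - 1L) / target_rate
  t_out <- t_out[t_out <= t1 + 1e-12]
  if (inherits(series, "euler_trajectory")) {
    cols <- c("roll_deg", "pitch_deg", "yaw_deg")
    out <- lapply(series[cols], function(x)
      wrap_deg(approx(series$t_s, unwrap_deg(x), xout = t_out)$y))
    new_euler_trajectory(tibble(t_s = t_out, roll_deg = out$roll_deg,
                                pitch_deg = out$pitch_deg, yaw_deg = out$yaw_deg),
                         rate = target_rate, frame = attr(series, "frame"))
  } else {
    tibble(t_s = t_out,
           x = approx(series$t_s, series$x, xout = t_out)$y,
           y = approx(series$t_s, series$y, xout = t_out)$y,
           z = approx(series$t_s, series$z, xout = t_out)$y)
  }
}

#' Merge the three components onto a common uniform grid
#'
#' After cropping, interpolates accelerometer, gyroscope and magnetometer
#' onto one uniform grid at `rate` (default 52 Hz, the accelerometer and
#' gyroscope rate; this is where the 100 Hz magnetometer is downsampled).
#'
#' @param recording a cropped `marg_recording`.
#' @param rate common grid rate in Hz.
#' @return a tibble `t_s, ax, ay, az, gx, gy, gz, mx, my, mz` with a `rate`
#'   attribute, ready for [run_filter()].
#' @export
merge_components <- function(recording, rate = 52) {
  comps <- recording[c("accel", "gyro", "mag")]
  t0 <- max(vapply(comps, function(d) min(d$t_s), numeric(1)))
  t1 <- min(vapply(comps, function(d) max(d$t_s), numeric(1)))
  if (t0 >= t1) abort("component time spans do not overlap; cannot merge")
  ## one shared grid from the common origin: interpolating each component onto
  ## different per-component grids would time-shift them against each other
  t_grid <- t0 + (seq_len(floor((t1 - t0) * rate) + 1L) - 1L) / rate
  t_grid <- t_grid[t_grid <= t1 + 1e-12]
  interp <- function(d) {
    vapply(c("x", "y", "z"), function(cc) approx(d$t_s, d[[cc]], xout = t_grid)$y,
           numeric(length(t_grid)))
  }
  a <- interp(comps$accel); g <- interp(comps$gyro); m <- interp(comps$mag)
  out <- tibble(
    t_s = t_grid,
    ax = a[, 1], ay = a[, 2], az = a[, 3],
    gx = g[, 1], gy = g[, 2], gz = g[, 3],
    mx = m[, 1], my = m[, 2], mz = m[, 3]
  )
  structure(out, rate = rate, placement = recording$placement, origin = t0)
}

#' Cross-correlation synchronization of two orientation series
#'
#' The two systems are triggered independently, so their clocks differ by an
#' unknown lag. The lag is estimated as the argmax of the normalized
#' cross-correlation between one Euler channel of the two series (default:
#' the channel with the greatest reference circular variance, where the
#' movement's distinct signal features live), refined to sub-sample precision
#' by parabolic interpolation of the correlation peak. Correlation is
#' computed on the circular (cosine/sine) embedding of the angles, which is
#' invariant to the +/-180 seam and robust to the 180-degree pitch/yaw flips
#' that Euler series exhibit when roll passes the gimbal singularity.
#'
#' @param sensor,reference `euler_trajectory` objects at the same rate.
#' @param max_lag maximum |lag| searched, seconds.
#' @param channel `"roll_deg"`, `"pitch_deg"`, `"yaw_deg"`, or `NULL` to pick
#'   the highest-variance reference channel.
#' @param lag manual override: skip estimation and report this lag.
#' @return a `sync_result` with fields `lag` (seconds; sensor clock minus
#'   reference clock for the same event), `score` (peak normalized
#'   correlation), `channel`, and `at_boundary` (TRUE if the peak sat at the
#'   search edge, recorded as a warning sign).
#' @export
synchronize <- function(sensor, reference, max_lag = 2, channel = NULL,
                        lag = NULL) {
  fr <- traj_rate(reference); fs <- traj_rate(sensor)
  if (abs(fr - fs) > 1e-6) abort("resample both series to a common rate before synchronizing")
  if (!is.null(lag)) {
    return(structure(list(lag = lag, score = NA_real_, channel = channel %||% "manual",
                          at_boundary = FALSE), class = "sync_result"))
  }
  chans <- c("roll_deg", "pitch_deg", "yaw_deg")
  circ_var <- function(x) {
    r <- deg2rad(x)
    1 - sqrt(mean(cos(r))^2 + mean(sin(r))^2)
  }
  if (is.null(channel)) {
    v <- vapply(chans, function(ch) circ_var(reference[[ch]]), numeric(1))
    channel <- chans[which.max(v)]
  }
  if (circ_var(reference[[channel]]) < 1e-8 && circ_var(sensor[[channel]]) < 1e-8) {
    abort("all channels below the variance floor (static series); cannot synchronize")
  }
  ## circular embedding: wrap-invariant and robust to gimbal flips
  rr <- deg2rad(reference[[channel]]); sr <- deg2rad(sensor[[channel]])
  r2 <- cbind(cos(rr), sin(rr)); s2 <- cbind(cos(sr), sin(sr))
  f <- fr
  base_shift <- sensor$t_s[1L] - reference$t_s[1L]
  ## candidate integer shifts M: sensor index j matches reference index j + M,
  ## corresponding to lag = base_shift - M / f
  Ms <- seq.int(ceiling((base_shift - max_lag) * f), floor((base_shift + max_lag) * f))
  nr <- nrow(r2); ns <- nrow(s2)
  score <- vapply(Ms, function(M) {
    j0 <- max(1L, 1L - M); j1 <- min(ns, nr - M)
    if (j1 - j0 + 1L < max(16L, 0.1 * min(nr, ns))) return(NA_real_)
    sj <- s2[j0:j1, , drop = FALSE]
    rj <- r2[(j0 + M):(j1 + M), , drop = FALSE]
    sj <- sweep(sj, 2L, colMeans(sj)); rj <- sweep(rj, 2L, colMeans(rj))
    den <- sqrt(sum(sj^2) * sum(rj^2))
    if (den == 0) return(NA_real_)
    sum(sj * rj) / den
  }, numeric(1))
  if (all(is.na(score))) abort("no candidate lag leaves enough overlap to correlate")
  i <- which.max(score)
  at_boundary <- i == 1L || i == length(Ms)
  ## parabolic sub-sample refinement around the peak
  delta <- 0
  if (!at_boundary && !anyNA(score[c(i - 1L, i + 1L)])) {
    y1 <- score[i - 1L]; y2 <- score[i]; y3 <- score[i + 1L]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > 1e-15) delta <- 0.5 * (y1 - y3) / den
  }
  M_star <- Ms[i] + delta
  structure(list(lag = base_shift - M_star / f, score = score[i],
                 channel = channel, at_boundary = at_boundary),
            class = "sync_result")
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf("<sync_result lag = %.4f s on %s (score %.3f%s)>\n",
              x$lag, x$channel, x$score,
              if (isTRUE(x$at_boundary)) ", peak at search boundary" else ""))
  invisible(x)
}

#' Shift a trajectory's clock by a synchronization lag
#'
#' @param traj an `euler_trajectory` (or any tibble with `t_s`).
#' @param sync a `sync_result` from [synchronize()], or a numeric lag in
#'   seconds.
#' @return the trajectory with `t_s - lag`, i.e. moved onto the reference
#'   clock.
#' @export
apply_sync <- function(traj, sync) {
  lag <- if (inherits(sync, "sync_result")) sync$lag else sync
  traj$t_s <- traj$t_s - lag
  traj
}

#' Estimate and apply the static heading (yaw) offset
#'
#' The fused orientations live in the sensor's geomagnetic global frame
#' (heading relative to magnetic north); the reference system's lab frame is
#' rotated from it by a constant angle about the vertical. Over a static
#' window the offset is observable as the mean yaw discrepancy:
#' `estimate_heading_offset()` takes the circular mean of
#' `reference yaw - sensor yaw` over the window (series must already be
#' synchronized). `apply_heading_correction()` left-multiplies every sample's
#' DCM by the vertical-axis rotation through that angle and re-derives the
#' Euler angles, so pitch and roll change only through the re-derivation
#' (identically zero change when the offset is zero).
#'
#' @param sensor,reference synchronized `euler_trajectory` objects.
#' @param window length-2 numeric, seconds on the common (reference) clock;
#'   must lie in a static segment and span at least 0.5 s.
#' @param traj an `euler_trajectory` to correct.
#' @param corr a `heading_correction`.
#' @return `estimate_heading_offset()` a `heading_correction` with
#'   `delta_psi` (degrees, wrapped) and `window`;
#'   `apply_heading_correction()` the corrected trajectory.
#' @export
estimate_heading_offset <- function(sensor, reference, window) {
  if (diff(window) < 0.5) abort("heading-offset window must span at least 0.5 s")
  sel_r <- reference$t_s >= window[1] & reference$t_s <= window[2]
  if (!any(sel_r)) abort("window lies outside the reference series")
  tr <- reference$t_s[sel_r]
  if (tr[1] < min(sensor$t_s) || tr[length(tr)] > max(sensor$t_s)) {
    abort("window lies (partly) outside the sensor series; synchronize first")
  }
  sy <- approx(sensor$t_s, unwrap_deg(sensor$yaw_deg), xout = tr)$y
  d <- wrap_deg(reference$yaw_deg[sel_r] - sy)
  structure(list(delta_psi = wrap_deg(circular_mean_deg(d)), window = window),
            class = "heading_correction")
}

#' @rdname estimate_heading_offset
#' @export
apply_heading_correction <- function(traj, corr) {
  if (!inherits(corr, "heading_correction")) abort("`corr` must be a heading_correction")
  q_corr <- quat_from_axis_angle(c(0, 0, 1), corr$delta_psi)
  if (inherits(traj, "quat_trajectory")) {
    q <- quat_multiply(q_corr, as.matrix(traj[, c("qw", "qx", "qy", "qz")]))
    traj$qw <- q[, 1]; traj$qx <- q[, 2]; traj$qy <- q[, 3]; traj$qz <- q[, 4]
    return(traj)
  }
  q <- euler_xyz_to_quat(traj$roll_deg, traj$pitch_deg, traj$yaw_deg)
  e <- quat_to_euler_xyz(quat_multiply(q_corr, q))
  traj$roll_deg <- e$roll_deg
  traj$pitch_deg <- e$pitch_deg
  traj$yaw_deg <- e$yaw_deg
  traj
}

#' Baseline a trajectory to zero over a static window
#'
#' Subtracts the per-angle circular mean over a static window from every
#' sample and rewraps, so both systems share a zero reference and absolute
#' orientations become comparable.
#'
#' @param traj an `euler_trajectory`.
#' @param window length-2 numeric, seconds; must intersect the series.
#' @return the baselined trajectory.
#' @export
baseline_to_zero <- function(traj, window) {
  sel <- traj$t_s >= window[1] & traj$t_s <= window[2]
  if (!any(sel)) abort("baseline window lies outside the series")
  for (ch in c("roll_deg", "pitch_deg", "yaw_deg")) {
    traj[[ch]] <- wrap_deg(traj[[ch]] - circular_mean_deg(traj[[ch]][sel]))
  }
  traj
}

#' Put a sensor/reference pair on a common grid
#'
#' Interpolates the sensor trajectory onto the reference time grid over the
#' overlap of their spans (angles unwrapped for interpolation, rewrapped
#' after). Both outputs have identical `t_s`.
#'
#' @param sensor,reference `euler_trajectory` objects on the same clock.
#' @return a list with elements `sensor` and `reference`.
#' @export
align_pair <- function(sensor, reference) {
  t0 <- max(sensor$t_s[1L], reference$t_s[1L])
  t1 <- min(max(sensor$t_s), max(reference$t_s))
  if (t0 >= t1) abort("sensor and reference spans do not overlap")
  sel <- reference$t_s >= t0 & reference$t_s <= t1
  tr <- reference$t_s[sel]
  cols <- c("roll_deg", "pitch_deg", "yaw_deg")
  s <- lapply(sensor[cols], function(x) wrap_deg(approx(sensor$t_s, unwrap_deg(x), xout = tr)$y))
  list(
    sensor = new_euler_trajectory(
      tibble(t_s = tr, roll_deg = s$roll_deg, pitch_deg = s$pitch_deg, yaw_deg = s$yaw_deg),
      rate = traj_rate(reference), frame = attr(sensor, "frame")),
    reference = new_euler_trajectory(as_tibble(reference[sel, ]),
                                     rate = traj_rate(reference),
                                     frame = attr(reference, "frame"))
  )
}
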