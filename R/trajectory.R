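#' Movement profiles
#'
#' A movement profile describes one exercise set the way the validation
#' protocol prescribes it: a static lead-in pose, `reps_per_set` smooth
#' repetition cycles, and a static tail pose. Amplitudes are peak Euler-angle
#' excursions per channel (degrees); the repetition shape is a raised cosine,
#' which dwells at end-range rather than sweeping through it like a sinusoid.
#'
#' Presets sketch the four analysed exercises. They are stylized: each drives
#' the field-typical primary axes (pitch/X and yaw/Z dominate, roll/Y is
#' secondary) except `chair_dip`, whose roll excursion deliberately passes
#' through the 90-degree gimbal singularity to reproduce the pitch/yaw error
#' blow-up seen on thigh and ankle sensors.
#'
#' @param name one of `"squat"`, `"pushup"`, `"good_morning"`, `"chair_dip"`,
#'   `"custom"`. Presets fill `amplitude`/`rep_period`; pass `amplitude` to
#'   override.
#' @param reps_per_set repetitions per set (default 10).
#' @param sets number of sets in the protocol (default 3); `make_trajectory()`
#'   generates one set, cohort helpers iterate over sets.
#' @param rep_period seconds per repetition.
#' @param static_lead,static_tail seconds of static pose before/after the reps.
#' @param amplitude named numeric vector `c(roll, pitch, yaw)` of peak
#'   excursions in degrees; entries must be < 180.
#' @param base_pose length-3 `c(roll, pitch, yaw)` degrees: the static
#'   reference pose the set starts and ends in.
#' @return an object of class `movement_profile`.
#' @examples
#' movement_profile("squat")
#' @export
movement_profile <- function(name = "custom",
                             reps_per_set = 10,
                             sets = 3,
                             rep_period = 3,
                             static_lead = 5,
                             static_tail = 5,
                             amplitude = NULL,
                             base_pose = c(roll = 0, pitch = 0, yaw = 0)) {
  name <- match.arg(name, c("custom", "squat", "pushup", "good_morning", "chair_dip"))
  presets <- list(
    squat        = c(roll = 5,   pitch = 40, yaw = 10),
    pushup       = c(roll = 8,   pitch = 30, yaw = 6),
    good_morning = c(roll = 6,   pitch = 70, yaw = 8),
    chair_dip    = c(roll = 100, pitch = 20, yaw = 12),
    custom       = c(roll = 0,   pitch = 0,  yaw = 0)
  )
  if (is.null(amplitude)) amplitude <- presets[[name]]
  amplitude <- amplitude[c("roll", "pitch", "yaw")]
  if (anyNA(amplitude)) abort("`amplitude` needs named entries roll, pitch, yaw")
  if (any(!is.finite(amplitude)) || any(abs(amplitude) >= 180)) {
    abort("amplitudes must be finite and < 180 degrees (Euler ambiguity)")
  }
  if (reps_per_set < 1) abort("`reps_per_set` must be >= 1")
  stopifnot_scalar_number(rep_period, "rep_period", min = 1e-6)
  stopifnot_scalar_number(static_lead, "static_lead", min = 0)
  stopifnot_scalar_number(static_tail, "static_tail", min = 0)
  axes <- c(roll = "Y", pitch = "X", yaw = "Z")
  structure(
    list(
      name = name, reps_per_set = as.integer(reps_per_set),
      sets = as.integer(sets), rep_period = rep_period,
      static_lead = static_lead, static_tail = static_tail,
      amplitude = amplitude,
      primary_axes = unname(axes[names(amplitude)[abs(amplitude) > 0]]),
      base_pose = rep_len(base_pose, 3L)
    ),
    class = "movement_profile"
  )
}

#' @export
print.movement_profile <- function(x, ...) {
  cat(sprintf(
    "<movement_profile '%s': %d x %d reps @ %.2gs, statics %g/%g s, amplitude r/p/y = %g/%g/%g deg>\n",
    x$name, x$sets, x$reps_per_set, x$rep_period, x$static_lead, x$static_tail,
    x$amplitude["roll"], x$amplitude["pitch"], x$amplitude["yaw"]
  ))
  invisible(x)
}

profile_duration <- function(profile) {
  profile$static_lead + profile$reps_per_set * profile$rep_period + profile$static_tail
}

#' Generate a ground-truth orientation trajectory for one exercise set
#'
#' Produces the unobserved state both measurement systems are driven from: a
#' uniformly sampled unit-quaternion series (segment frame relative to lab
#' frame). The set is `static_lead` seconds at the base pose, then
#' `reps_per_set` raised-cosine repetition cycles of the profile amplitudes,
#' then `static_tail` seconds static again.
#'
#' With `amplitude_jitter > 0` the per-channel amplitudes are multiplied by
#' `1 + jitter * N(0,1)` draws, emulating between-participant execution
#' variability; `seed` makes that draw reproducible. With the default jitter
#' of 0 the trajectory is fully deterministic.
#'
#' @param profile a [movement_profile()].
#' @param rate sampling rate in Hz (default 250, the reference-system rate).
#' @param seed integer seed for the jitter draw (ignored when jitter is 0).
#' @param amplitude_jitter relative SD of amplitude variability (default 0).
#' @return a `ground_truth` tibble with columns `t_s, qw, qx, qy, qz` and a
#'   `rate` attribute; quaternion rows are unit-norm.
#' @examples
#' gt <- make_trajectory(movement_profile("squat"), rate = 52)
#' nrow(gt)
#' @export
make_trajectory <- function(profile, rate = 250, seed = NULL, amplitude_jitter = 0) {
  if (!inherits(profile, "movement_profile")) abort("`profile` must be a movement_profile")
  stopifnot_scalar_number(rate, "rate", min = 1e-6)
  amp <- profile$amplitude
  if (amplitude_jitter > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    amp <- amp * (1 + amplitude_jitter * rnorm(3))
    amp <- pmin(pmax(amp, -179), 179)
  }
  duration <- profile_duration(profile)
  n <- floor(duration * rate) + 1L
  t <- (seq_len(n) - 1L) / rate
  move <- t >= profile$static_lead & t < profile$static_lead +
    profile$reps_per_set * profile$rep_period
  s <- numeric(n)
  u <- (t[move] - profile$static_lead) / profile$rep_period
  s[move] <- 0.5 * (1 - cos(2 * pi * (u %% 1)))
  base <- profile$base_pose
  q <- euler_xyz_to_quat(base[1] + amp["roll"] * s,
                         base[2] + amp["pitch"] * s,
                         base[3] + amp["yaw"] * s)
  out <- tibble(t_s = t, qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4])
  structure(out, rate = rate, profile = profile, class = c("ground_truth", class(out)))
}

#' Generate a calibration tumble trajectory
#'
#' Magnetometer ellipsoid calibration needs samples spanning many
#' non-coplanar field directions; a single exercise set traces only a narrow
#' arc of orientations and cannot constrain the fit. This generates the
#' standard calibration maneuver instead: a spherical-spiral rotation (yaw
#' sweeping several turns while pitch sweeps between +/-`pitch_max` and roll
#' wobbles) whose body-frame field directions cover the sphere.
#'
#' @param duration seconds (default 20).
#' @param rate sampling rate in Hz (default 100).
#' @param turns yaw revolutions over the sweep (default 3).
#' @param pitch_max half-range of the pitch sweep in degrees (default 75).
#' @return a `ground_truth` tibble, as from [make_trajectory()].
#' @export
make_tumble_trajectory <- function(duration = 20, rate = 100, turns = 3,
                                   pitch_max = 75) {
  n <- floor(duration * rate) + 1L
  t <- (seq_len(n) - 1L) / rate
  u <- t / duration
  q <- euler_xyz_to_quat(
    40 * sin(2 * pi * 5 * u),
    pitch_max * sin(pi * (2 * u - 0.5)),
    360 * turns * u
  )
  out <- tibble(t_s = t, qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4])
  structure(out, rate = rate, class = c("ground_truth", class(out)))
}

ground_truth_quat <- function(truth) {
  as.matrix(truth[, c("qw", "qx", "qy", "qz")])
}

#' Euler-angle view of a ground-truth trajectory
#'
#' @param truth a `ground_truth` tibble from [make_trajectory()].
#' @return an `euler_trajectory` tibble (`t_s, roll_deg, pitch_deg, yaw_deg`).
#' @export
truth_to_euler <- function(truth) {
  e <- quat_to_euler_xyz(ground_truth_quat(truth))
  new_euler_trajectory(
    tibble(t_s = truth$t_s, roll_deg = e$roll_deg, pitch_deg = e$pitch_deg,
           yaw_deg = e$yaw_deg),
    rate = attr(truth, "rate"), frame = "lab"
  )
}
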