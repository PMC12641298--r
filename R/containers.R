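#' Data containers
#'
#' Two light containers carry data through the pipeline.
#'
#' An `euler_trajectory` is a tibble with columns `t_s`, `roll_deg`,
#' `pitch_deg`, `yaw_deg` on a uniform time grid, plus `rate` (Hz) and `frame`
#' ("sensor-geomagnetic", "lab", or "reference-lab") attributes. Angles are
#' wrapped to (-180, 180].
#'
#' A `marg_recording` bundles the three asynchronous component streams of one
#' sensor: tibbles `accel` (g), `gyro` (deg/s) and `mag` (gauss), each with
#' columns `t_s, x, y, z` and strictly increasing timestamps sampled at their
#' own rates, together with `placement` (C, LW, RW, LT, RT, LA, RA),
#' `handedness` ("left" or "right") and clipping counts.
#'
#' @param data a tibble with the required columns.
#' @param rate sampling rate in Hz.
#' @param frame frame tag for the trajectory.
#' @name containers
NULL

#' @rdname containers
#' @export
new_euler_trajectory <- function(data, rate, frame = "lab") {
  need <- c("t_s", "roll_deg", "pitch_deg", "yaw_deg")
  if (!all(need %in% names(data))) {
    abort(paste("euler trajectory needs columns", paste(need, collapse = ", ")))
  }
  data <- as_tibble(data)
  data[c("roll_deg", "pitch_deg", "yaw_deg")] <-
    lapply(data[c("roll_deg", "pitch_deg", "yaw_deg")], wrap_deg)
  structure(data, rate = rate, frame = frame,
            class = c("euler_trajectory", class(as_tibble(data))))
}

traj_rate <- function(traj) {
  r <- attr(traj, "rate")
  if (is.null(r)) {
    dt <- diff(traj$t_s)
    r <- 1 / stats::median(dt)
  }
  r
}

new_marg_recording <- function(accel, gyro, mag, placement = "C",
                               handedness = "right", rates = NULL,
                               clipped = c(accel = 0L, gyro = 0L, mag = 0L),
                               seed = NULL) {
  comps <- list(accel = accel, gyro = gyro, mag = mag)
  for (nm in names(comps)) {
    cc <- comps[[nm]]
    if (!all(c("t_s", "x", "y", "z") %in% names(cc))) {
      abort(sprintf("component '%s' needs columns t_s, x, y, z", nm))
    }
    if (is.unsorted(cc$t_s, strictly = TRUE)) {
      abort(sprintf("component '%s' timestamps must be strictly increasing", nm))
    }
    comps[[nm]] <- as_tibble(cc)
  }
  structure(
    list(accel = comps$accel, gyro = comps$gyro, mag = comps$mag,
         placement = placement, handedness = handedness,
         rates = rates, clipped = clipped, seed = seed),
    class = "marg_recording"
  )
}

#' @export
print.marg_recording <- function(x, ...) {
  span <- function(d) sprintf("[%.3f, %.3f] s, n=%d", min(d$t_s), max(d$t_s), nrow(d))
  cat(sprintf("<marg_recording placement=%s handedness=%s>\n", x$placement, x$handedness))
  cat("  accel:", span(x$accel), "\n  gyro: ", span(x$gyro),
      "\n  mag:  ", span(x$mag), "\n")
  if (any(x$clipped > 0)) cat("  clipped samples:", paste(names(x$clipped),
                                                          x$clipped, collapse = ", "), "\n")
  invisible(x)
}

component_matrix <- function(component) {
  as.matrix(component[, c("x", "y", "z")])
}
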