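#' Tidy and glance methods
#'
#' broom-style accessors for the package's fitted objects.
#'
#' `tidy()` on a `marg_pipeline` gives one row per Euler angle with the RMSE
#' and its accuracy category; `glance()` gives a one-row run summary (lag,
#' heading offset, gimbal fraction, calibration diagnostics). `tidy()` on a
#' `mag_calibration` gives the hard-iron components and the soft-iron inverse
#' eigenvalues; `glance()` the field magnitude and the calibrated-norm
#' coefficient of variation. `tidy()` on a `sync_result` is its one-row
#' summary.
#'
#' @param x the object.
#' @param ... unused.
#' @return a tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.marg_pipeline <- function(x, ...) {
  tibble(
    angle = c("roll", "pitch", "yaw"),
    rmse = c(x$rmse$roll, x$rmse$pitch, x$rmse$yaw),
    category = classify_rmse(c(x$rmse$roll, x$rmse$pitch, x$rmse$yaw)),
    gimbal_fraction = x$rmse$gimbal_fraction,
    n_samples = x$rmse$n_samples
  )
}

#' @rdname tidiers
#' @export
glance.marg_pipeline <- function(x, ...) {
  tibble(
    placement = x$placement,
    lag_s = x$sync$lag,
    sync_score = x$sync$score,
    sync_channel = x$sync$channel,
    heading_offset_deg = x$heading$delta_psi,
    gimbal_fraction = x$rmse$gimbal_fraction,
    gyro_bias_norm_dps = if (!is.null(x$gyro_calibration))
      sqrt(sum(x$gyro_calibration$bias^2)) else NA_real_,
    mag_norm_cv = if (!is.null(x$mag_calibration)) x$mag_calibration$norm_cv else NA_real_
  )
}

#' @rdname tidiers
#' @export
tidy.mag_calibration <- function(x, ...) {
  tibble(
    term = c("hard_iron_x", "hard_iron_y", "hard_iron_z",
             "soft_iron_eigen_1", "soft_iron_eigen_2", "soft_iron_eigen_3"),
    estimate = c(x$hard_iron, sort(eigen(x$soft_iron_inv, symmetric = TRUE,
                                         only.values = TRUE)$values))
  )
}

#' @rdname tidiers
#' @export
glance.mag_calibration <- function(x, ...) {
  tibble(field_magnitude = x$field_magnitude, norm_cv = x$norm_cv,
         det_soft_iron_inv = det(x$soft_iron_inv))
}

#' @rdname tidiers
#' @export
tidy.sync_result <- function(x, ...) {
  tibble(lag_s = x$lag, score = x$score, channel = x$channel,
         at_boundary = x$at_boundary)
}
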