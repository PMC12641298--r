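#' Magnetometer hard/soft-iron ellipsoid calibration
#'
#' Nearby ferromagnetic material distorts a magnetometer's readings so that,
#' as the sensor rotates through a constant ambient field, the sample cloud
#' traces an offset ellipsoid instead of an origin-centred sphere. The
#' additive offset is the hard-iron term; the linear shape distortion is the
#' soft-iron term. `fit_magnetometer_ellipsoid()` inverts both
#' retrospectively from the recording itself.
#'
#' The fit solves the classic 9-parameter linear least-squares quadric
#' `x'Mx + 2k'x = 1` for the symmetric matrix `M` and vector `k`, then factors
#' it into centre `c = -solve(M, k)` (the hard iron) and the inverse soft-iron
#' map `A = sqrtm(M / s)` with `s = 1 + c'Mc`, so that `A %*% (m - c)` lies on
#' a sphere. `A` is rescaled to `det(A) = 1`, with the implied sphere radius
#' reported as `field_magnitude`; the fusion filter uses only the field
#' direction, so any fixed normalization is equivalent.
#'
#' A coplanar or otherwise degenerate sample cloud (e.g. rotation about a
#' single axis only) cannot constrain an ellipsoid; the fit then raises an
#' explicit degenerate-geometry error rather than silently returning an
#' identity calibration.
#'
#' @param samples an n x 3 matrix, or a tibble with columns `x, y, z`, or a
#'   `marg_recording` (its `mag` component is used). Units gauss.
#' @param cal a `mag_calibration` object.
#' @return `fit_magnetometer_ellipsoid()` returns a `mag_calibration` with
#'   fields `soft_iron_inv` (3 x 3, det = 1), `hard_iron` (gauss),
#'   `field_magnitude` (gauss) and `norm_cv` (coefficient of variation of the
#'   calibrated norms over the fitting data). `apply_mag_calibration()`
#'   returns calibrated samples in the same shape it was given.
#' @examples
#' sph <- quat_rotate(quat_normalize(matrix(rnorm(400), ncol = 4)), c(1, 0, 0))
#' raw <- sph %*% diag(c(1.2, 1, 0.8)) + rep(c(0.3, -0.1, 0.05), each = 100)
#' fit_magnetometer_ellipsoid(raw)
#' @export
fit_magnetometer_ellipsoid <- function(samples) {
  m <- mag_samples_matrix(samples)
  if (nrow(m) < 10L) abort("need at least 10 magnetometer samples to fit an ellipsoid")
  x <- m[, 1]; y <- m[, 2]; z <- m[, 3]
  D <- cbind(x^2, y^2, z^2, 2 * x * y, 2 * x * z, 2 * y * z, 2 * x, 2 * y, 2 * z)
  qr_D <- qr(D)
  if (qr_D$rank < 9L) {
    abort("degenerate magnetometer geometry: samples do not span an ellipsoid (coplanar or too few directions)")
  }
  u <- qr.coef(qr_D, rep(1, nrow(D)))
  M <- matrix(c(u[1], u[4], u[5],
                u[4], u[2], u[6],
                u[5], u[6], u[3]), nrow = 3L)
  eM <- eigen(M, symmetric = TRUE)
  if (any(eM$values <= 0) ||
      max(eM$values) / min(eM$values) > 1e6) {
    abort("degenerate magnetometer geometry: fitted quadric is not an ellipsoid")
  }
  centre <- -solve(M, u[7:9])
  s <- 1 + drop(centre %*% M %*% centre)
  E <- M / s                       # (m - c)' E (m - c) = 1
  eE <- eigen(E, symmetric = TRUE)
  A <- eE$vectors %*% diag(sqrt(eE$values)) %*% t(eE$vectors)  # sqrtm(E)
  scale <- det(A)^(1 / 3)
  A <- A / scale                    # det(A) = 1
  field_magnitude <- 1 / scale      # |A (m - c)| for exact data
  cal <- structure(list(soft_iron_inv = A, hard_iron = unname(centre),
                        field_magnitude = field_magnitude, norm_cv = NA_real_),
                   class = "mag_calibration")
  norms <- sqrt(rowSums(apply_mag_calibration(m, cal)^2))
  cal$norm_cv <- sd(norms) / mean(norms)
  cal
}

mag_samples_matrix <- function(samples) {
  if (inherits(samples, "marg_recording")) samples <- samples$mag
  if (is.data.frame(samples)) samples <- as.matrix(samples[, c("x", "y", "z")])
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1L)
  storage.mode(samples) <- "double"
  samples
}

#' @rdname fit_magnetometer_ellipsoid
#' @export
apply_mag_calibration <- function(samples, cal) {
  if (!inherits(cal, "mag_calibration")) abort("`cal` must be a mag_calibration")
  if (inherits(samples, "marg_recording")) {
    m <- component_matrix(samples$mag)
    out <- sweep(m, 2L, cal$hard_iron) %*% t(cal$soft_iron_inv)
    samples$mag$x <- out[, 1]; samples$mag$y <- out[, 2]; samples$mag$z <- out[, 3]
    samples$mag_calibration <- cal
    return(samples)
  }
  was_df <- is.data.frame(samples)
  tcol <- if (was_df && "t_s" %in% names(samples)) samples$t_s else NULL
  m <- mag_samples_matrix(samples)
  out <- sweep(m, 2L, cal$hard_iron) %*% t(cal$soft_iron_inv)
  if (was_df) {
    res <- tibble(x = out[, 1], y = out[, 2], z = out[, 3])
    if (!is.null(tcol)) res <- tibble(t_s = tcol, x = out[, 1], y = out[, 2], z = out[, 3])
    res
  } else {
    colnames(out) <- c("x", "y", "z")
    out
  }
}

#' @export
print.mag_calibration <- function(x, ...) {
  cat("<mag_calibration>\n  hard iron (gauss): ",
      paste(sprintf("%.4f", x$hard_iron), collapse = ", "),
      sprintf("\n  field magnitude: %.4f gauss; calibrated-norm CV: %.2e\n",
              x$field_magnitude, x$norm_cv))
  invisible(x)
}

#' Static gyroscope bias estimation
#'
#' Consumer gyroscopes carry a slowly varying additive bias that integrates
#' into orientation drift. The protocol's 5-second static poses make it
#' observable: over a static window the true angular velocity is zero, so the
#' per-axis mean reading *is* the bias. `estimate_gyro_bias()` takes the mean
#' over a window that must pass a static gate (per-axis RMS of the
#' mean-removed signal below `gate_dps`); with `window = NULL` it finds the
#' quietest `min_window`-second span itself, which is robust to the unknown
#' clock offset between sensor and reference. `apply_gyro_calibration()`
#' subtracts the bias from the full stream.
#'
#' @param recording a `marg_recording` (or a bare gyro tibble `t_s, x, y, z`).
#' @param window length-2 numeric, seconds in the gyro stream's own clock;
#'   `NULL` to auto-detect the quietest window.
#' @param gate_dps static gate: maximum per-axis RMS of the detrended gyro
#'   signal in the window, deg/s.
#' @param min_window minimum window length in seconds (>= 1).
#' @param cal a `gyro_calibration`.
#' @return `estimate_gyro_bias()` returns a `gyro_calibration` with fields
#'   `bias` (deg/s) and `static_window`; `apply_gyro_calibration()` the
#'   recording with the bias subtracted.
#' @export
estimate_gyro_bias <- function(recording, window = NULL, gate_dps = 3,
                               min_window = 3) {
  gyro <- if (inherits(recording, "marg_recording")) recording$gyro else as_tibble(recording)
  if (min_window < 1) abort("`min_window` must be >= 1 second")
  if (is.null(window)) {
    window <- find_quietest_window(gyro, min_window)
  }
  if (diff(window) < 1) abort("static window must be at least 1 second long")
  sel <- gyro$t_s >= window[1] & gyro$t_s <= window[2]
  if (!any(sel)) abort("no gyro samples inside the static window")
  g <- component_matrix(gyro[sel, ])
  rms <- sqrt(colMeans(scale(g, scale = FALSE)^2))
  if (any(rms > gate_dps)) {
    ax <- c("x", "y", "z")[which.max(rms)]
    abort(sprintf(
      "window [%.2f, %.2f] s fails the static gate: %s-axis detrended RMS %.2f deg/s exceeds %.2f deg/s",
      window[1], window[2], ax, max(rms), gate_dps))
  }
  structure(list(bias = colMeans(g), static_window = window),
            class = "gyro_calibration")
}

find_quietest_window <- function(gyro, len) {
  t0 <- min(gyro$t_s); t1 <- max(gyro$t_s)
  if (t1 - t0 < len) abort("gyro stream shorter than the minimum static window")
  starts <- seq(t0, t1 - len, by = 0.25)
  g <- component_matrix(gyro)
  rms_at <- vapply(starts, function(s) {
    sel <- gyro$t_s >= s & gyro$t_s <= s + len
    sum(colMeans(scale(g[sel, , drop = FALSE], scale = FALSE)^2))
  }, numeric(1))
  s <- starts[which.min(rms_at)]
  c(s, s + len)
}

#' @rdname estimate_gyro_bias
#' @export
apply_gyro_calibration <- function(recording, cal) {
  if (!inherits(cal, "gyro_calibration")) abort("`cal` must be a gyro_calibration")
  recording$gyro$x <- recording$gyro$x - cal$bias[1]
  recording$gyro$y <- recording$gyro$y - cal$bias[2]
  recording$gyro$z <- recording$gyro$z - cal$bias[3]
  recording$gyro_calibration <- cal
  recording
}
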