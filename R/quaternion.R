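#' Quaternion algebra
#'
#' Orientations are unit quaternions, scalar-first, stored row-wise in an
#' n x 4 numeric matrix with columns `w, x, y, z`. A quaternion `q` maps
#' sensor/segment-frame coordinates to lab-frame coordinates:
#' `v_lab = q (0, v_sensor) q*`. `q` and `-q` denote the same orientation and
#' are treated as equal by all angle comparisons.
#'
#' @param w,x,y,z numeric vectors (recycled to a common length).
#' @param q,a,b quaternion matrices (n x 4 or 1 x 4; 1-row inputs recycle).
#' @param v n x 3 matrix (or length-3 vector) of 3-vectors.
#' @param axis length-3 axis (need not be unit length).
#' @param angle_deg rotation angle in degrees.
#' @return `quat()`, `quat_multiply()`, `quat_conjugate()`, `quat_normalize()`
#'   and `quat_from_axis_angle()` return n x 4 quaternion matrices;
#'   `quat_rotate()` returns an n x 3 matrix; `quat_angle_deg()` a numeric
#'   vector of geodesic angles in degrees (sign-invariant).
#' @examples
#' q <- quat_from_axis_angle(c(0, 0, 1), 90)
#' quat_rotate(q, c(1, 0, 0))   # ~ (0, 1, 0)
#' @name quaternion
NULL

#' @rdname quaternion
#' @export
quat <- function(w, x = 0, y = 0, z = 0) {
  m <- cbind(w = w, x = x, y = y, z = z)
  storage.mode(m) <- "double"
  m
}

#' @rdname quaternion
#' @export
quat_identity <- function(n = 1L) {
  quat(rep(1, n), rep(0, n), rep(0, n), rep(0, n))
}

as_quat_matrix <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1L)
  if (ncol(q) != 4L) abort("quaternions must have 4 columns (w, x, y, z)")
  colnames(q) <- c("w", "x", "y", "z")
  q
}

#' @rdname quaternion
#' @export
quat_normalize <- function(q) {
  q <- as_quat_matrix(q)
  n <- sqrt(rowSums(q^2))
  if (any(n == 0)) abort("cannot normalize a zero quaternion")
  q / n
}

#' @rdname quaternion
#' @export
quat_conjugate <- function(q) {
  q <- as_quat_matrix(q)
  q[, 2:4] <- -q[, 2:4]
  q
}

#' @rdname quaternion
#' @export
quat_multiply <- function(a, b) {
  a <- as_quat_matrix(a); b <- as_quat_matrix(b)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  quat(
    a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
    a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
    a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
    a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  )
}

#' @rdname quaternion
#' @export
quat_rotate <- function(q, v) {
  q <- as_quat_matrix(q)
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
  if (nrow(q) == 1L && nrow(v) > 1L) q <- q[rep(1L, nrow(v)), , drop = FALSE]
  if (nrow(v) == 1L && nrow(q) > 1L) v <- v[rep(1L, nrow(q)), , drop = FALSE]
  p <- quat_multiply(quat_multiply(q, cbind(0, v)), quat_conjugate(q))
  p[, 2:4, drop = FALSE]
}

#' @rdname quaternion
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  half <- deg2rad(angle_deg) / 2
  quat(cos(half), axis[1] * sin(half), axis[2] * sin(half), axis[3] * sin(half))
}

#' @rdname quaternion
#' @export
quat_angle_deg <- function(a, b) {
  a <- as_quat_matrix(a); b <- as_quat_matrix(b)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  d <- pmin(1, abs(rowSums(a * b)))
  rad2deg(2 * acos(d))
}

## Flip signs so consecutive rows stay in the same hemisphere (continuity for
## interpolation and finite differencing).
quat_hemisphere_align <- function(q) {
  q <- as_quat_matrix(q)
  if (nrow(q) < 2L) return(q)
  flips <- cumprod(c(1, ifelse(rowSums(q[-1L, , drop = FALSE] *
                                         q[-nrow(q), , drop = FALSE]) < 0, -1, 1)))
  q * flips
}

## Normalized-linear interpolation of a dense quaternion series onto new times.
## Adequate for the sample spacings used here (inter-sample angles << 1 rad).
quat_interp <- function(t, q, t_out) {
  q <- quat_hemisphere_align(as_quat_matrix(q))
  if (any(t_out < t[1L] - 1e-9) || any(t_out > t[length(t)] + 1e-9)) {
    abort("quaternion interpolation requested outside the sampled span")
  }
  out <- vapply(1:4, function(j) approx(t, q[, j], xout = t_out, rule = 2)$y,
                numeric(length(t_out)))
  quat_normalize(matrix(out, ncol = 4L))
}

## Body-frame angular velocity (rad/s) of a uniformly sampled quaternion
## series, via central differences: omega = 2 vec(q* qdot).
quat_angular_velocity <- function(t, q) {
  q <- quat_hemisphere_align(as_quat_matrix(q))
  n <- nrow(q)
  if (n < 3L) abort("need at least 3 samples to differentiate")
  dt <- t[2L] - t[1L]
  qdot <- rbind(
    (q[2L, ] - q[1L, ]) / dt,
    (q[3:n, , drop = FALSE] - q[1:(n - 2L), , drop = FALSE]) / (2 * dt),
    (q[n, ] - q[n - 1L, ]) / dt
  )
  w <- quat_multiply(quat_conjugate(q), qdot)
  2 * w[, 2:4, drop = FALSE]
}
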