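#' Euler XYZ, quaternion and DCM conversions
#'
#' The package uses the XYZ Euler sequence read extrinsically -- rotations
#' about the fixed lab x, then y, then z axes, i.e.
#' `R = Rz(yaw) %*% Ry(roll) %*% Rx(pitch)` with `v_lab = R %*% v_sensor` --
#' with the axis-to-name mapping used in segment-orientation reporting for
#' this device class: the X angle is pitch (theta), the Y angle is roll (phi)
#' and the Z angle is yaw (psi). Roll is the *middle* angle, so the
#' gimbal-lock singularity occurs as |roll| approaches 90 degrees, exactly
#' where pitch and yaw estimates become unstable. The extrinsic reading (as
#' opposed to intrinsic X-then-Y-then-Z) is forced by the heading semantics of
#' the alignment stage: yaw must be the rotation about the *lab* vertical, so
#' that left-multiplying a DCM by a vertical-axis rotation shifts yaw alone
#' and leaves static pitch/roll untouched. This axis-to-name mapping is
#' unusual (many texts put roll on X); it is centralized here and nowhere
#' else.
#'
#' At the singularity (|roll| = 90 within numerical tolerance) the free angle
#' is assigned to yaw, pitch is set to zero, and the `gimbal` flag is set;
#' nothing is thrown.
#'
#' @param roll_deg,pitch_deg,yaw_deg numeric vectors of angles in degrees.
#' @param q quaternion matrix (n x 4, scalar-first).
#' @param dcm a 3 x 3 rotation matrix.
#' @return `euler_xyz_to_quat()` an n x 4 quaternion matrix;
#'   `quat_to_euler_xyz()` a tibble with columns `roll_deg`, `pitch_deg`,
#'   `yaw_deg`, `gimbal`; `quat_to_dcm()` a 3 x 3 matrix (single quaternion);
#'   `dcm_to_quat()` a 1 x 4 quaternion; `dcm_to_euler_xyz()` a one-row tibble.
#' @examples
#' quat_to_euler_xyz(euler_xyz_to_quat(10, 20, 30))
#' @name euler
NULL

#' @rdname euler
#' @export
euler_xyz_to_quat <- function(roll_deg, pitch_deg, yaw_deg) {
  n <- max(length(roll_deg), length(pitch_deg), length(yaw_deg))
  hp <- deg2rad(rep_len(pitch_deg, n)) / 2
  hr <- deg2rad(rep_len(roll_deg, n)) / 2
  hy <- deg2rad(rep_len(yaw_deg, n)) / 2
  qx <- quat(cos(hp), sin(hp), 0, 0)
  qy <- quat(cos(hr), 0, sin(hr), 0)
  qz <- quat(cos(hy), 0, 0, sin(hy))
  quat_multiply(quat_multiply(qz, qy), qx)
}

#' @rdname euler
#' @export
quat_to_euler_xyz <- function(q) {
  q <- quat_normalize(as_quat_matrix(q))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  ## elements of R = Rz(yaw) Ry(roll) Rx(pitch)
  r11 <- 1 - 2 * (y^2 + z^2)
  r12 <- 2 * (x * y - w * z)
  r13 <- 2 * (x * z + w * y)
  r21 <- 2 * (x * y + w * z)
  r31 <- 2 * (x * z - w * y)
  r32 <- 2 * (y * z + w * x)
  r33 <- 1 - 2 * (x^2 + y^2)
  s <- pmin(1, pmax(-1, -r31))
  gimbal <- abs(s) > 1 - 1e-9
  roll <- asin(s)
  pitch <- atan2(r32, r33)
  yaw <- atan2(r21, r11)
  if (any(gimbal)) {
    ## free angle to yaw, pitch set to zero (documented convention)
    pitch[gimbal] <- 0
    yaw[gimbal] <- atan2(-r12[gimbal], sign(s[gimbal]) * r13[gimbal])
  }
  tibble(
    roll_deg = unname(wrap_deg(rad2deg(roll))),
    pitch_deg = unname(wrap_deg(rad2deg(pitch))),
    yaw_deg = unname(wrap_deg(rad2deg(yaw))),
    gimbal = unname(gimbal)
  )
}

#' @rdname euler
#' @export
quat_to_dcm <- function(q) {
  q <- quat_normalize(as_quat_matrix(q))
  if (nrow(q) != 1L) abort("quat_to_dcm() takes a single quaternion")
  w <- q[1, 1]; x <- q[1, 2]; y <- q[1, 3]; z <- q[1, 4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

#' @rdname euler
#' @export
dcm_to_quat <- function(dcm) {
  if (!is.matrix(dcm) || any(dim(dcm) != 3L)) abort("`dcm` must be 3 x 3")
  if (abs(det(dcm) - 1) > 1e-6) abort("`dcm` is not a proper rotation (det != 1)")
  R <- dcm
  ## Shepperd's method: pick the numerically largest pivot
  tr <- sum(diag(R))
  cand <- c(tr, R[1, 1], R[2, 2], R[3, 3])
  i <- which.max(cand)
  if (i == 1L) {
    s <- sqrt(1 + tr) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (i == 2L) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (i == 3L) {
    s <- sqrt(1 - R[1, 1] + R[2, 2] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 - R[1, 1] - R[2, 2] + R[3, 3]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, s / 4)
  }
  quat_normalize(quat(q[1], q[2], q[3], q[4]))
}

#' @rdname euler
#' @export
dcm_to_euler_xyz <- function(dcm) {
  quat_to_euler_xyz(dcm_to_quat(dcm))
}
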