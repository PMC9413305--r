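#' Quaternion algebra (Hamilton convention, scalar first)
#'
#' Minimal quaternion toolkit used by the attitude estimator. Quaternions are
#' plain numeric vectors `c(w, x, y, z)` with the scalar part first, following
#' the Hamilton convention (`i*j = k`, right-handed). Unit quaternions encode
#' the rotation of the sensor frame relative to the initial (static) frame.
#'
#' @param a,b,q Numeric length-4 quaternions, scalar part first.
#' @return `quat_multiply()` the Hamilton product `a %*% b` as a length-4
#'   vector; `quat_conjugate()` the conjugate; `quat_normalize()` the unit
#'   quaternion; `quat_identity()` the identity rotation.
#' @examples
#' quat_multiply(c(0, 1, 0, 0), c(0, 0, 1, 0))  # i * j = k
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' @rdname quat_multiply
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' @rdname quat_multiply
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n == 0) abort("cannot normalize a zero quaternion", class = "instep_numeric_error")
  q / n
}

#' @rdname quat_multiply
#' @export
quat_identity <- function() c(1, 0, 0, 0)

#' Axis-angle quaternion
#'
#' @param axis Rotation axis (any nonzero 3-vector; normalized internally).
#' @param angle Rotation angle in radians.
#' @return Unit quaternion rotating by `angle` about `axis`.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Rotate a 3-vector by a unit quaternion
#'
#' Computes the vector part of `q (0, v) q*`, i.e. applies the rotation
#' encoded by `q` to `v`. The norm of `v` is preserved.
#'
#' @param q Unit quaternion (checked to within 1e-6).
#' @param v Numeric 3-vector.
#' @return Rotated 3-vector.
#' @export
quat_rotate <- function(q, v) {
  if (abs(sum(q^2) - 1) > 1e-6) {
    abort("`q` must be a unit quaternion", class = "instep_numeric_error")
  }
  # expanded form of q (0,v) q*; identical to the two Hamilton products
  t2 <- 2 * c(q[3] * v[3] - q[4] * v[2],
              q[4] * v[1] - q[2] * v[3],
              q[2] * v[2] - q[3] * v[1])
  v + q[1] * t2 + c(q[3] * t2[3] - q[4] * t2[2],
                    q[4] * t2[1] - q[2] * t2[3],
                    q[2] * t2[2] - q[3] * t2[1])
}

#' Rotation matrix of a unit quaternion
#'
#' @param q Unit quaternion.
#' @return 3x3 rotation matrix `R` with `R %*% v == quat_rotate(q, v)`.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' One-step quaternion attitude update from angular rate
#'
#' Advances the orientation by one sampling interval using the quaternion
#' kinematic equation: the derivative `0.5 * q x (0, omega)` is scaled by `dt`,
#' added to the previous quaternion, and the result renormalized, so the
#' returned quaternion is always unit-norm.
#'
#' @param prev Previous unit quaternion (sensor-to-initial frame).
#' @param omega Angular rate, rad/s, length-3 (sensor frame).
#' @param dt Sampling interval in seconds, > 0.
#' @return Updated unit quaternion.
#' @examples
#' q <- quat_identity()
#' for (k in 1:100) q <- update_attitude(q, c(0, 0, pi / 2), 0.01)
#' q  # ~ 90 degrees about z
#' @export
update_attitude <- function(prev, omega, dt) {
  stopifnot(dt > 0)
  dq <- 0.5 * quat_multiply(prev, c(0, omega))
  quat_normalize(prev + dq * dt)
}
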