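#' Propagate attitude along a stream and rotate accelerations into the
#' initial frame
#'
#' Starting from the identity quaternion (the initial, static sensor frame),
#' the orientation is advanced sample by sample with [update_attitude()] and
#' each acceleration sample is rotated into the initial frame
#' (`a' = q (0, a) q*`). The angular rate driving each step is the average of
#' the two samples bounding the interval — the same trapezoid idea used for
#' the velocity integration — which keeps the attitude error second order in
#' the sampling interval even while the rate is changing.
#'
#' @param records Calibrated SI records tibble (`ax..az` m/s^2, `gx..gz`
#'   rad/s).
#' @param config An [imu_config()] (supplies the sampling interval).
#' @return A tibble with columns `t`, rotated `ax, ay, az` (initial frame),
#'   and the per-sample attitude quaternion `qw, qx, qy, qz`. Empty input
#'   yields an empty tibble.
#' @export
propagate_attitude <- function(records, config = imu_config()) {
  stopifnot(inherits(config, "imu_config"))
  n <- nrow(records)
  if (n == 0) {
    return(tibble(t = numeric(), ax = numeric(), ay = numeric(), az = numeric(),
                  qw = numeric(), qx = numeric(), qy = numeric(), qz = numeric()))
  }
  dt <- 1 / config$sample_rate_hz
  w <- cbind(records$gx, records$gy, records$gz)
  q <- matrix(0, n, 4)
  q[1, ] <- quat_identity()
  if (n > 1) {
    for (k in 2:n) {
      omega <- 0.5 * (w[k - 1, ] + w[k, ])
      q[k, ] <- if (all(omega == 0)) q[k - 1, ] else update_attitude(q[k - 1, ], omega, dt)
    }
  }
  a <- cbind(records$ax, records$ay, records$az)
  tibble(
    t = records$t %||% (seq_len(n) - 1) * dt,
    !!!setNames(as.data.frame(rotate_rows(q, a)), c("ax", "ay", "az")),
    qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4]
  )
}

# vectorized q (0,v) q* over matched rows of quaternions and vectors
rotate_rows <- function(q, v) {
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  tx <- 2 * (y * v[, 3] - z * v[, 2])
  ty <- 2 * (z * v[, 1] - x * v[, 3])
  tz <- 2 * (x * v[, 2] - y * v[, 1])
  cbind(v[, 1] + w * tx + (y * tz - z * ty),
        v[, 2] + w * ty + (z * tx - x * tz),
        v[, 3] + w * tz + (x * ty - y * tx))
}
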