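#' Synthetic instep-kick profile
#'
#' Describes the commanded kinematics of a simulated instep kick (performed
#' without striking a ball): a static lead, a backswing that lifts the foot to
#' `backswing_height`, a forward swing whose speed peaks at `peak_speed` at
#' the low point of the arc, and a follow-through that decelerates to rest.
#' Defaults reproduce a representative adult instep kick: apex 0.756 m, peak
#' foot speed 7.47 m/s, total path about 3.63 m.
#'
#' The trajectory lives mostly in the y-z plane (forward = +y, up = +z) with
#' a small lateral x excursion. The follow-through length is solved
#' numerically so the total path length meets `path_length_target`; peak
#' speed and apex height are met exactly by construction (the knots of the
#' piecewise-quintic trajectory carry those values).
#'
#' @param backswing_height Apex height of the pull-back, m.
#' @param peak_speed Maximum foot speed, m/s, reached at the low point.
#' @param path_length_target Total 3D path length, m.
#' @param kick_duration Duration of the moving part, s.
#' @param static_lead Number of stationary samples before the kick (must be at
#'   least the pipeline's static window).
#' @param tail Number of stationary samples appended after the follow-through.
#' @param orientation_sweep Total foot pitch rotation over the swing, rad.
#' @param backswing_distance Horizontal pull-back distance, m.
#' @param low_point_forward Forward offset of the low point from the start, m.
#' @param lateral Peak lateral excursion, m.
#' @param follow_height Foot height at the end of the follow-through, m.
#' @return An object of class `kick_profile`.
#' @export
kick_profile <- function(backswing_height = 0.756,
                         peak_speed = 7.47,
                         path_length_target = 3.63,
                         kick_duration = 1.4,
                         static_lead = 600,
                         tail = 100,
                         orientation_sweep = 0.7,
                         backswing_distance = 0.55,
                         low_point_forward = 0.25,
                         lateral = 0.05,
                         follow_height = 0.55) {
  p <- list(backswing_height = backswing_height, peak_speed = peak_speed,
            path_length_target = path_length_target, kick_duration = kick_duration,
            static_lead = as.integer(static_lead), tail = as.integer(tail),
            orientation_sweep = orientation_sweep,
            backswing_distance = backswing_distance,
            low_point_forward = low_point_forward,
            lateral = lateral, follow_height = follow_height)
  pos <- c("backswing_height", "peak_speed", "path_length_target", "kick_duration",
           "static_lead", "backswing_distance", "follow_height")
  if (!all(vapply(p[pos], function(x) is.numeric(x) && x > 0, logical(1)))) {
    abort("kick profile quantities must be positive", class = "instep_profile_error")
  }
  structure(p, class = "kick_profile")
}

#' Sensor noise and deviation model for the simulator
#'
#' Forward model applied when inverting a ground-truth trajectory into raw
#' IMU samples: per-axis scale `L` and bias `b` of the accelerometer
#' (`G = L(g + b)`, g units), additive Gaussian noise on both sensors, an
#' initial mounting tilt (roll/pitch drawn uniformly in
#' `[-initial_tilt, initial_tilt]`), optional gyro bias, and 16-bit
#' quantization at the configured full scales.
#'
#' Defaults emulate a consumer MEMS IMU after rough factory trim: accel noise
#' 0.05 m/s^2, gyro noise 0.2 deg/s, per-axis bias within 0.05 g, scale within
#' 2% of unity, mounting tilt up to 10 degrees, quantization on.
#'
#' @param accel_sigma Accelerometer noise SD, m/s^2.
#' @param gyro_sigma Gyroscope noise SD, rad/s (default 0.2 deg/s).
#' @param accel_bias Per-axis accelerometer bias, g units.
#' @param accel_scale Per-axis scale factors (diagonal of `L`).
#' @param gyro_bias Per-axis gyroscope bias, rad/s (default zero).
#' @param initial_tilt Maximum mounting tilt, rad (default 10 degrees).
#' @param quantize Quantize to signed 16-bit counts (default `TRUE`).
#' @param seed Integer seed driving every random draw, or `NULL` to use the
#'   current RNG state.
#' @return An object of class `imu_noise`.
#' @export
imu_noise <- function(accel_sigma = 0.05,
                      gyro_sigma = 0.2 * pi / 180,
                      accel_bias = c(0.030, -0.025, 0.040),
                      accel_scale = c(1.015, 0.985, 1.008),
                      gyro_bias = c(0, 0, 0),
                      initial_tilt = 10 * pi / 180,
                      quantize = TRUE,
                      seed = NULL) {
  if (accel_sigma < 0 || gyro_sigma < 0) {
    abort("noise sigmas must be non-negative", class = "instep_input_error")
  }
  structure(list(accel_sigma = accel_sigma, gyro_sigma = gyro_sigma,
                 accel_bias = accel_bias, accel_scale = accel_scale,
                 gyro_bias = gyro_bias, initial_tilt = initial_tilt,
                 quantize = isTRUE(quantize), seed = seed),
            class = "imu_noise")
}

# quintic polynomial with prescribed position/velocity/acceleration at both
# ends; returns coefficients c0..c5 of p(t) = sum c_k t^k on [0, T]
quintic_coef <- function(p0, v0, a0, p1, v1, a1, T) {
  c0 <- p0; c1 <- v0; c2 <- a0 / 2
  A <- matrix(c(T^3, T^4, T^5,
                3 * T^2, 4 * T^3, 5 * T^4,
                6 * T, 12 * T^2, 20 * T^3), 3, byrow = TRUE)
  rhs <- c(p1 - (c0 + c1 * T + c2 * T^2),
           v1 - (c1 + 2 * c2 * T),
           a1 - 2 * c2)
  c(c0, c1, c2, solve(A, rhs))
}

quintic_eval <- function(cf, t) {
  pos <- cf[1] + t * (cf[2] + t * (cf[3] + t * (cf[4] + t * (cf[5] + t * cf[6]))))
  vel <- cf[2] + t * (2 * cf[3] + t * (3 * cf[4] + t * (4 * cf[5] + t * 5 * cf[6])))
  acc <- 2 * cf[3] + t * (6 * cf[4] + t * (12 * cf[5] + t * 20 * cf[6]))
  list(pos = pos, vel = vel, acc = acc)
}

minjerk <- function(s) 10 * s^3 - 15 * s^4 + 6 * s^5
minjerk_d <- function(s) 30 * s^2 - 60 * s^3 + 30 * s^4

# evaluate the three-phase swing at motion times tm (0 .. T1+T2+T3)
eval_swing <- function(knots, tm) {
  phase_of <- findInterval(tm, c(knots$t1, knots$t2), left.open = TRUE) + 1L
  pos <- vel <- acc <- matrix(0, length(tm), 3)
  for (ph in 1:3) {
    idx <- which(phase_of == ph)
    if (!length(idx)) next
    tloc <- tm[idx] - c(0, knots$t1, knots$t2)[ph]
    for (ax in 1:3) {
      ev <- quintic_eval(knots$coef[[ph]][[ax]], tloc)
      pos[idx, ax] <- ev$pos; vel[idx, ax] <- ev$vel; acc[idx, ax] <- ev$acc
    }
  }
  list(pos = pos, vel = vel, acc = acc)
}

make_knots <- function(profile, follow_distance) {
  dt_snap <- function(x, dt) round(x / dt) * dt
  T <- profile$kick_duration
  t1 <- 0.45 * T; t2 <- t1 + 0.25 * T; t3 <- T
  p0 <- c(0, 0, 0)
  p1 <- c(profile$lateral, -profile$backswing_distance, profile$backswing_height)
  p2 <- c(0, profile$low_point_forward, 0)
  p3 <- c(profile$lateral, profile$low_point_forward + follow_distance, profile$follow_height)
  v2 <- c(0, profile$peak_speed, 0)
  zero <- c(0, 0, 0)
  seg <- function(pa, va, aa, pb, vb, ab, Tseg) {
    lapply(1:3, function(ax) quintic_coef(pa[ax], va[ax], aa[ax], pb[ax], vb[ax], ab[ax], Tseg))
  }
  list(t1 = t1, t2 = t2, t3 = t3,
       coef = list(seg(p0, zero, zero, p1, zero, zero, t1),
                   seg(p1, zero, zero, p2, v2, zero, t2 - t1),
                   seg(p2, v2, zero, p3, zero, zero, t3 - t2)))
}

#' Analytic ground-truth kick trajectory
#'
#' Builds a C2 (continuously differentiable acceleration-free of jumps)
#' piecewise-quintic trajectory realizing a [kick_profile()]: static lead,
#' backswing to the commanded apex (zero velocity and acceleration at the
#' apex knot, so the apex height is exact), forward swing through the low
#' point where the speed equals the commanded peak exactly (the knot is a
#' critical point of speed), follow-through to rest, and a static tail. The
#' foot orientation pitches smoothly about the lateral (x) axis through
#' `orientation_sweep` following a minimum-jerk time course.
#'
#' The free follow-through distance is solved with `uniroot()` so the total
#' path length meets the profile target. Profiles whose durations cannot
#' accommodate the commanded speeds raise an `instep_profile_error`.
#'
#' @param profile A [kick_profile()].
#' @param dt Sampling interval, s (default 0.01, i.e. 100 Hz).
#' @return A `kick_truth` tibble: `t`, position `px..pz` (m), velocity
#'   `vx..vz` (m/s), acceleration `ax..az` (m/s^2), attitude quaternion
#'   `qw..qz` (sensor-to-world, yaw-free) and body angular rate `wx..wz`
#'   (rad/s).
#' @examples
#' truth <- kick_truth()
#' max(sqrt(truth$vx^2 + truth$vy^2 + truth$vz^2))  # 7.47 exactly
#' @export
kick_truth <- function(profile = kick_profile(), dt = 0.01) {
  stopifnot(inherits(profile, "kick_profile"), dt > 0)
  # snap the motion duration to the sample grid so the knots land on samples
  n_motion <- round(profile$kick_duration / dt)
  if (n_motion < 20) {
    abort("kick_duration too short for the sampling interval", class = "instep_profile_error")
  }
  profile$kick_duration <- n_motion * dt
  # crude feasibility: each phase's mean speed must be well below the peak
  kn0 <- make_knots(profile, follow_distance = 1)
  chord <- function(a, b) sqrt(sum((b - a)^2))
  p1 <- c(profile$lateral, -profile$backswing_distance, profile$backswing_height)
  p2 <- c(0, profile$low_point_forward, 0)
  if (chord(p1, p2) / (kn0$t2 - kn0$t1) > profile$peak_speed) {
    abort("infeasible profile: downswing too short for the commanded peak speed",
          class = "instep_profile_error")
  }
  tm <- seq(0, profile$kick_duration, by = dt)
  path_of <- function(df) {
    sw <- eval_swing(make_knots(profile, df), tm)
    sum(sqrt(rowSums(diff(sw$pos)^2)))
  }
  # path length is not monotone in the follow-through distance (short
  # follow-throughs make the quintic wiggle); search upward from the minimum
  lo <- stats::optimize(path_of, c(0.05, 3))$minimum
  hi <- 8
  if (path_of(lo) > profile$path_length_target || path_of(hi) < profile$path_length_target) {
    abort("infeasible profile: path-length target unreachable with this geometry",
          class = "instep_profile_error")
  }
  follow <- uniroot(function(d) path_of(d) - profile$path_length_target,
                    c(lo, hi), tol = 1e-10)$root
  knots <- make_knots(profile, follow)
  sw <- eval_swing(knots, tm)
  speed <- sqrt(rowSums(sw$vel^2))
  if (max(speed) > profile$peak_speed * (1 + 1e-9)) {
    abort("infeasible profile: interior speed exceeds the commanded peak",
          class = "instep_profile_error")
  }
  # orientation: minimum-jerk pitch about x through the sweep
  s <- tm / profile$kick_duration
  phi <- profile$orientation_sweep * minjerk(s)
  phidot <- profile$orientation_sweep * minjerk_d(s) / profile$kick_duration
  lead <- profile$static_lead
  tail <- profile$tail
  n <- lead + length(tm) + tail
  t_all <- (seq_len(n) - 1) * dt
  idx_m <- lead + seq_along(tm)
  P <- V <- A <- matrix(0, n, 3)
  P[idx_m, ] <- sw$pos; V[idx_m, ] <- sw$vel; A[idx_m, ] <- sw$acc
  if (tail > 0) P[(lead + length(tm) + 1):n, ] <- matrix(sw$pos[length(tm), ], tail, 3, byrow = TRUE)
  phi_all <- c(rep(0, lead), phi, rep(phi[length(phi)], tail))
  w_all <- c(rep(0, lead), phidot, rep(0, tail))
  out <- tibble(
    t = t_all,
    px = P[, 1], py = P[, 2], pz = P[, 3],
    vx = V[, 1], vy = V[, 2], vz = V[, 3],
    ax = A[, 1], ay = A[, 2], az = A[, 3],
    qw = cos(phi_all / 2), qx = sin(phi_all / 2), qy = 0, qz = 0,
    wx = w_all, wy = 0, wz = 0
  )
  structure(out, profile = profile, dt = dt, follow_distance = follow,
            class = c("kick_truth", class(out)))
}

#' Static (rest-only) ground truth
#'
#' Convenience constructor for a motionless trajectory, useful for testing
#' the pipeline's behaviour on purely static captures.
#'
#' @param n Number of samples.
#' @param dt Sampling interval, s.
#' @return A `kick_truth` tibble at rest at the origin.
#' @export
static_truth <- function(n = 700, dt = 0.01) {
  out <- tibble(t = (seq_len(n) - 1) * dt,
                px = 0, py = 0, pz = 0, vx = 0, vy = 0, vz = 0,
                ax = 0, ay = 0, az = 0,
                qw = 1, qx = 0, qy = 0, qz = 0, wx = 0, wy = 0, wz = 0)
  structure(out, dt = dt, class = c("kick_truth", class(out)))
}

#' Invert a ground-truth trajectory into raw IMU samples
#'
#' Applies the inverse of the reconstruction model: the world-frame kinematic
#' acceleration plus gravity is rotated into the (tilted) sensor frame to give
#' the specific force, the accelerometer deviation model `G = L(g + b)` and
#' Gaussian noise are applied, body angular rates get bias and noise, and the
#' result is optionally quantized to signed 16-bit counts at the configured
#' full-scale ranges (values beyond full scale are clipped with a warning).
#' The mounting tilt is drawn once per call; all randomness flows from
#' `noise$seed`, so equal seeds give bit-identical streams.
#'
#' @param truth A [kick_truth()] tibble.
#' @param noise An [imu_noise()] model.
#' @param config An [imu_config()].
#' @return If `noise$quantize`, a tibble of signed 16-bit counts
#'   (`ax..az, gx..gz`); otherwise an SI records tibble (`t, ax..gz`).
#' @export
simulate_imu <- function(truth, noise = imu_noise(), config = imu_config()) {
  stopifnot(inherits(noise, "imu_noise"), inherits(config, "imu_config"))
  if (!is.null(noise$seed)) withr::local_seed(noise$seed)
  n <- nrow(truth)
  tilt_r <- runif(1, -noise$initial_tilt, noise$initial_tilt)
  tilt_p <- runif(1, -noise$initial_tilt, noise$initial_tilt)
  # rest orientation chosen yaw-free in the Rz Ry Rx sense, so the pipeline's
  # two-angle leveling can recover the world frame exactly
  q_tilt <- quat_multiply(quat_from_axis_angle(c(1, 0, 0), -tilt_r),
                          quat_from_axis_angle(c(0, 1, 0), -tilt_p))
  qm <- cbind(truth$qw, truth$qx, truth$qy, truth$qz)
  qws <- t(apply(qm, 1, function(q) quat_multiply(q_tilt, q)))
  aw <- cbind(truth$ax, truth$ay, truth$az + STANDARD_GRAVITY)
  qconj <- cbind(qws[, 1], -qws[, 2], -qws[, 3], -qws[, 4])
  f_s <- rotate_rows(qconj, aw)
  G <- sweep(sweep(f_s / STANDARD_GRAVITY, 2, noise$accel_bias, "+"), 2, noise$accel_scale, "*")
  a_meas <- G * STANDARD_GRAVITY + matrix(rnorm(3 * n, sd = noise$accel_sigma), n, 3)
  w_s <- cbind(truth$wx, truth$wy, truth$wz)
  g_meas <- sweep(w_s, 2, noise$gyro_bias, "+") + matrix(rnorm(3 * n, sd = noise$gyro_sigma), n, 3)
  if (!noise$quantize) {
    return(tibble(t = truth$t,
                  ax = a_meas[, 1], ay = a_meas[, 2], az = a_meas[, 3],
                  gx = g_meas[, 1], gy = g_meas[, 2], gz = g_meas[, 3]))
  }
  a_lsb <- config$accel_full_scale_g * STANDARD_GRAVITY / 32768
  g_lsb <- config$gyro_full_scale_dps * pi / 180 / 32768
  quant <- function(x, lsb) {
    k <- round(x / lsb)
    if (any(k > 32767) || any(k < -32768)) {
      warn("specific force or rate exceeds full scale; clipping to 16-bit range")
      k <- pmin(pmax(k, -32768), 32767)
    }
    k
  }
  tibble(ax = quant(a_meas[, 1], a_lsb), ay = quant(a_meas[, 2], a_lsb),
         az = quant(a_meas[, 3], a_lsb),
         gx = quant(g_meas[, 1], g_lsb), gy = quant(g_meas[, 2], g_lsb),
         gz = quant(g_meas[, 3], g_lsb))
}

#' Static multi-orientation calibration set
#'
#' Generates the static recording the sphere-model calibration consumes:
#' unit-gravity readings at `n_orientations` quasi-uniform orientations
#' (Fibonacci sphere), pushed through the same scale/bias/noise forward model
#' as [simulate_imu()].
#'
#' @param noise An [imu_noise()] model (quantization is not applied; the
#'   calibration input contract is g units).
#' @param n_orientations Number of distinct orientations (>= 6).
#' @param samples_per Static samples recorded at each orientation.
#' @return A tibble with columns `orientation, ax, ay, az` (g units).
#' @export
simulate_calibration_set <- function(noise = imu_noise(), n_orientations = 24,
                                     samples_per = 25) {
  stopifnot(inherits(noise, "imu_noise"))
  if (n_orientations < 6) {
    abort("need at least 6 orientations for a well-conditioned fit",
          class = "instep_input_error")
  }
  if (!is.null(noise$seed)) withr::local_seed(noise$seed)
  i <- seq_len(n_orientations)
  golden <- pi * (3 - sqrt(5))
  z <- 1 - (2 * i - 1) / n_orientations
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(golden * i), r * sin(golden * i), z)
  rows <- dirs[rep(i, each = samples_per), , drop = FALSE]
  G <- sweep(sweep(rows, 2, noise$accel_bias, "+"), 2, noise$accel_scale, "*") +
    matrix(rnorm(3 * nrow(rows), sd = noise$accel_sigma / STANDARD_GRAVITY), nrow(rows), 3)
  tibble(orientation = rep(i, each = samples_per),
         ax = G[, 1], ay = G[, 2], az = G[, 3])
}

#' Use a ground-truth trajectory as a reference
#'
#' Reshapes a [kick_truth()] tibble into the reference-trajectory layout
#' (`t, x, y, z, vx, vy, vz`) consumed by [align_to_reference()] and
#' [compare_to_reference()].
#'
#' @param truth A [kick_truth()] tibble.
#' @return A reference tibble.
#' @export
as_reference <- function(truth) {
  tibble(t = truth$t, x = truth$px, y = truth$py, z = truth$pz,
         vx = truth$vx, vy = truth$vy, vz = truth$vz)
}

#' Write a ground-truth trajectory as a reference CSV
#'
#' Emits the `t, x, y, z, vx, vy, vz` reference format read by
#' [read_reference_csv()], serving the role of a camera-derived reference.
#'
#' @param truth A [kick_truth()] tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reference_csv <- function(truth, path) {
  out <- data.frame(t = truth$t, x = truth$px, y = truth$py, z = truth$pz,
                    vx = truth$vx, vy = truth$vy, vz = truth$vz)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
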