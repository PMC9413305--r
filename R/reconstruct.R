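#' Static gravity offset
#'
#' Mean acceleration over the leading static window, in initial-frame
#' coordinates. Subtracting this constant from the whole stream removes
#' gravity (and any residual accelerometer offset) because gravity is fixed
#' in the initial frame while the attitude tracking follows the sensor.
#'
#' @param accels Data frame with initial-frame `ax, ay, az` (m/s^2).
#' @param window Number of leading samples to average (must not exceed the
#'   stream length; all of them must be genuinely static).
#' @return Object of class `static_offset`: list with `offset` (3-vector,
#'   m/s^2) and `window`. A warning is raised when the offset norm is more
#'   than 5% away from standard gravity, which indicates a non-static
#'   capture.
#' @export
static_offset <- function(accels, window = 500) {
  n <- nrow(accels)
  if (n < window) {
    abort(sprintf("stream has %d samples but the static window needs %d", n, window),
          class = "instep_input_error")
  }
  idx <- seq_len(window)
  off <- c(mean(accels$ax[idx]), mean(accels$ay[idx]), mean(accels$az[idx]))
  nrm <- sqrt(sum(off^2))
  if (abs(nrm - STANDARD_GRAVITY) > 0.05 * STANDARD_GRAVITY) {
    warn(sprintf("static offset norm %.3f m/s^2 deviates >5%% from gravity; was the capture static?", nrm))
  }
  structure(list(offset = off, window = as.integer(window)), class = "static_offset")
}

#' Subtract the gravity offset from every sample
#'
#' @param accels Data frame with `ax, ay, az` in initial-frame coordinates.
#' @param offset A [static_offset()].
#' @return The data frame with the offset subtracted.
#' @export
remove_gravity <- function(accels, offset) {
  stopifnot(inherits(offset, "static_offset"))
  dplyr::mutate(accels,
                ax = .data$ax - offset$offset[1],
                ay = .data$ay - offset$offset[2],
                az = .data$az - offset$offset[3])
}

#' Tilt correction: level the initial frame to the world frame
#'
#' The initial (static) sensor frame is generally tilted with respect to the
#' earth frame; the measured static gravity offset reveals the tilt. Roll and
#' pitch are recovered from the offset components
#' (`roll = atan2(offset_y, offset_z)`,
#' `pitch = -atan(offset_x / sqrt(offset_y^2 + offset_z^2))`, yaw fixed at 0 —
#' yaw is unobservable without a magnetometer) and composed as
#' `T = Rz(yaw) Ry(pitch) Rx(roll)`. Applying `T` to the offset aligns it
#' exactly with +z, so after correction "up" is the world vertical.
#'
#' @param offset A [static_offset()].
#' @return Object of class `tilt_correction`: list with `roll`, `pitch`,
#'   `yaw` (rad) and the 3x3 rotation matrix `R`.
#' @export
tilt_from_offset <- function(offset) {
  stopifnot(inherits(offset, "static_offset"))
  o <- offset$offset
  nrm <- sqrt(sum(o^2))
  if (abs(o[3]) < 0.05 * nrm) {
    abort("static offset has (near-)zero z component: sensor was on its side, tilt undefined",
          class = "instep_degenerate_error")
  }
  roll <- atan2(o[2], o[3])
  pitch <- -atan(o[1] / sqrt(o[2]^2 + o[3]^2))
  yaw <- 0
  Rx <- matrix(c(1, 0, 0,
                 0, cos(roll), -sin(roll),
                 0, sin(roll), cos(roll)), 3, byrow = TRUE)
  Ry <- matrix(c(cos(pitch), 0, sin(pitch),
                 0, 1, 0,
                 -sin(pitch), 0, cos(pitch)), 3, byrow = TRUE)
  Rz <- matrix(c(cos(yaw), -sin(yaw), 0,
                 sin(yaw), cos(yaw), 0,
                 0, 0, 1), 3, byrow = TRUE)
  structure(list(roll = roll, pitch = pitch, yaw = yaw, R = Rz %*% Ry %*% Rx),
            class = "tilt_correction")
}

#' Rotate every sample by the tilt-correction matrix
#'
#' @param accels Data frame with `ax, ay, az`.
#' @param tilt A [tilt_from_offset()] result.
#' @return The data frame with rotated components (norms preserved).
#' @export
apply_tilt <- function(accels, tilt) {
  stopifnot(inherits(tilt, "tilt_correction"))
  m <- cbind(accels$ax, accels$ay, accels$az) %*% t(tilt$R)
  dplyr::mutate(accels, ax = m[, 1], ay = m[, 2], az = m[, 3])
}

#' Gate small accelerations to zero
#'
#' Samples whose Euclidean norm falls below the gate are replaced by exact
#' zero vectors; everything else is untouched. Gating suppresses the residual
#' noise floor (incomplete gravity compensation, vibration) that would
#' otherwise accumulate through double integration, and produces the exact
#' zero runs the zero-velocity-update logic looks for.
#'
#' @param accels Data frame with gravity-free world-frame `ax, ay, az`.
#' @param gate Threshold in m/s^2.
#' @return The data frame with sub-gate samples zeroed.
#' @export
gate_accel <- function(accels, gate = 0.392) {
  nrm <- sqrt(accels$ax^2 + accels$ay^2 + accels$az^2)
  z <- nrm < gate
  dplyr::mutate(accels,
                ax = ifelse(z, 0, .data$ax),
                ay = ifelse(z, 0, .data$ay),
                az = ifelse(z, 0, .data$az))
}

new_kick_track <- function(df, config = NULL, offset = NULL, tilt = NULL) {
  structure(as_tibble(df),
            config = config, offset = offset, tilt = tilt,
            class = c("kick_track", class(as_tibble(df))))
}

#' Integrate gated accelerations into velocity and position
#'
#' Trapezoidal (averaged-sample) integration:
#' `v_i = v_(i-1) + (a_i + a_(i-1))/2 * dt`, and the same rule again from
#' velocity to position; the track starts at rest at the origin. Two
#' anti-drift mechanisms run during integration:
#' * zero-velocity update (ZUPT): when the last `zupt_run_length` gated
#'   accelerations are all exactly zero the sensor is declared stationary and
#'   the velocity is reset to zero (and stays zero until an above-gate
#'   acceleration arrives);
#' * inside a detected static run, any residual velocity whose norm is below
#'   `vel_gate` is clamped to zero.
#'
#' @param accels Data frame of gated world-frame accelerations `ax, ay, az`
#'   (m/s^2), uniformly sampled.
#' @param config An [imu_config()].
#' @return A `kick_track` tibble: `t, ax, ay, az, vx, vy, vz, px, py, pz,
#'   stationary`.
#' @export
integrate_track <- function(accels, config = imu_config()) {
  stopifnot(inherits(config, "imu_config"))
  n <- nrow(accels)
  dt <- 1 / config$sample_rate_hz
  a <- cbind(accels$ax, accels$ay, accels$az)
  v <- matrix(0, n, 3)
  p <- matrix(0, n, 3)
  stationary <- logical(n)
  zero_row <- rowSums(a != 0) == 0
  run <- if (n > 0 && zero_row[1]) 1L else 0L
  stationary[1] <- run >= config$zupt_run_length
  if (n > 1) {
    for (i in 2:n) {
      vi <- v[i - 1, ] + (a[i, ] + a[i - 1, ]) / 2 * dt
      run <- if (zero_row[i]) run + 1L else 0L
      if (run >= config$zupt_run_length) {
        stationary[i] <- TRUE
        vi <- c(0, 0, 0)
      } else if (run > 0L && stationary[i - 1] && sqrt(sum(vi^2)) < config$vel_gate) {
        # still inside a detected static run: clamp residual velocity
        stationary[i] <- TRUE
        vi <- c(0, 0, 0)
      }
      v[i, ] <- vi
      p[i, ] <- p[i - 1, ] + (v[i, ] + v[i - 1, ]) / 2 * dt
    }
  }
  new_kick_track(
    tibble(t = (seq_len(n) - 1) * dt,
           ax = a[, 1], ay = a[, 2], az = a[, 3],
           vx = v[, 1], vy = v[, 2], vz = v[, 3],
           px = p[, 1], py = p[, 2], pz = p[, 3],
           stationary = stationary),
    config = config
  )
}

#' Reconstruct the full kinematic track from raw IMU records
#'
#' Runs the whole strapdown pipeline: accelerometer calibration (optional),
#' quaternion attitude propagation and rotation into the initial frame,
#' static-window gravity offset estimation and subtraction, tilt leveling to
#' the world frame, acceleration gating, and trapezoidal double integration
#' with zero-velocity updates. The world frame has +z up and its origin at
#' the foot's static start; yaw is arbitrary (no magnetometer).
#'
#' @param records SI records tibble (`t, ax..az, gx..gz`), starting with at
#'   least `config$static_window` stationary samples.
#' @param model An `accel_calibration`, or `NULL` to skip calibration.
#' @param config An [imu_config()].
#' @param fix_gyro_bias Passed to [apply_calibration()]; also applied when
#'   `model` is `NULL` (bias is estimated from the static window).
#' @return A `kick_track` tibble (see [integrate_track()]), with the
#'   configuration, static offset and tilt stored as attributes and the
#'   attitude quaternion columns `qw..qz` retained.
#' @examples
#' truth <- kick_truth()
#' rec <- simulate_imu(truth, imu_noise(seed = 1))
#' trk <- reconstruct_track(counts_to_si(rec), model = NULL)
#' kick_metrics(trk)
#' @export
reconstruct_track <- function(records, model = identity_calibration(),
                              config = imu_config(), fix_gyro_bias = TRUE) {
  stopifnot(inherits(config, "imu_config"))
  if (nrow(records) < config$static_window) {
    abort(sprintf("stream has %d samples; the pipeline needs a static lead of %d",
                  nrow(records), config$static_window),
          class = "instep_input_error")
  }
  if (is.null(model)) model <- identity_calibration()
  cal <- apply_calibration(records, model, config, fix_gyro_bias = fix_gyro_bias)
  rot <- propagate_attitude(cal, config)
  off <- static_offset(rot, config$static_window)
  acc <- remove_gravity(rot, off)
  tilt <- tilt_from_offset(off)
  acc <- apply_tilt(acc, tilt)
  acc <- gate_accel(acc, config$accel_gate)
  track <- integrate_track(acc, config)
  track$qw <- rot$qw; track$qx <- rot$qx; track$qy <- rot$qy; track$qz <- rot$qz
  attr(track, "offset") <- off
  attr(track, "tilt") <- tilt
  track
}
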