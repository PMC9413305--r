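#' Pipeline configuration
#'
#' Bundles every tunable threshold and sensor-range constant used by the
#' reconstruction pipeline. Defaults correspond to a wide-range six-axis MEMS
#' IMU (ICM-20649 class) sampled at 100 Hz with full-scale ranges of +/-30 g
#' and +/-4000 deg/s, and to the motion-gating thresholds tuned for an instep
#' kick: accelerations below 0.392 m/s^2 (0.04 g) are treated as stationary
#' noise, and fifteen consecutive gated-zero samples trigger a zero-velocity
#' update.
#'
#' @param sample_rate_hz Sampling frequency in Hz.
#' @param accel_full_scale_g Accelerometer full-scale range in g (one side).
#' @param gyro_full_scale_dps Gyroscope full-scale range in deg/s (one side).
#' @param static_window Number of leading stationary samples used to estimate
#'   the gravity offset (and gyro bias). The recording must start at rest for
#'   at least this many samples.
#' @param accel_gate Acceleration gate in m/s^2: samples whose vector norm is
#'   below this are zeroed before integration.
#' @param vel_gate Velocity gate in m/s, applied as a secondary clamp inside
#'   detected static runs.
#' @param zupt_run_length Number of consecutive gated-zero acceleration
#'   samples required to declare the sensor stationary and reset velocity.
#' @param gyro_unit Unit of gyroscope values in input files: `"dps"`
#'   (degrees/s, the sensor-datasheet convention, default) or `"rad"`.
#'   All internal computation is in rad/s.
#'
#' @return An object of class `imu_config` (a named list).
#' @examples
#' cfg <- imu_config()
#' cfg$accel_gate
#' @export
imu_config <- function(sample_rate_hz = 100,
                       accel_full_scale_g = 30,
                       gyro_full_scale_dps = 4000,
                       static_window = 500,
                       accel_gate = 0.392,
                       vel_gate = 0.196,
                       zupt_run_length = 15,
                       gyro_unit = c("dps", "rad")) {
  gyro_unit <- match.arg(gyro_unit)
  cfg <- list(
    sample_rate_hz = sample_rate_hz,
    accel_full_scale_g = accel_full_scale_g,
    gyro_full_scale_dps = gyro_full_scale_dps,
    static_window = as.integer(static_window),
    accel_gate = accel_gate,
    vel_gate = vel_gate,
    zupt_run_length = as.integer(zupt_run_length),
    gyro_unit = gyro_unit
  )
  num <- cfg[setdiff(names(cfg), "gyro_unit")]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0, logical(1)))) {
    abort("all `imu_config` fields must be single positive finite numbers", class = "instep_config_error")
  }
  if (cfg$static_window < cfg$zupt_run_length) {
    abort("`static_window` must be at least `zupt_run_length`", class = "instep_config_error")
  }
  structure(cfg, class = "imu_config")
}

#' @export
print.imu_config <- function(x, ...) {
  cat("<imu_config>\n")
  cat(sprintf("  sample rate:     %g Hz (dt = %g s)\n", x$sample_rate_hz, 1 / x$sample_rate_hz))
  cat(sprintf("  full scale:      +/-%g g, +/-%g deg/s\n", x$accel_full_scale_g, x$gyro_full_scale_dps))
  cat(sprintf("  static window:   %d samples\n", x$static_window))
  cat(sprintf("  accel gate:      %g m/s^2\n", x$accel_gate))
  cat(sprintf("  velocity gate:   %g m/s\n", x$vel_gate))
  cat(sprintf("  ZUPT run length: %d samples\n", x$zupt_run_length))
  cat(sprintf("  file gyro unit:  %s\n", x$gyro_unit))
  invisible(x)
}

#' Read / write a pipeline configuration file
#'
#' Configurations are stored as flat YAML key-value files whose keys map
#' one-to-one to the [imu_config()] arguments. Unknown keys are rejected.
#'
#' @param path File path.
#' @return `read_imu_config()` returns an `imu_config`;
#'   `write_imu_config()` returns `path` invisibly.
#' @export
read_imu_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: '%s'", path), class = "instep_io_error")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(imu_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")),
          class = "instep_config_error")
  }
  do.call(imu_config, vals)
}

#' @param config An `imu_config` object.
#' @rdname read_imu_config
#' @export
write_imu_config <- function(config, path) {
  stopifnot(inherits(config, "imu_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}
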