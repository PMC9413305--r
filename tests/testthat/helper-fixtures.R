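# shared fixtures: small streams and noise models used across test files

G0 <- 9.80665

# zero-noise, zero-tilt, identity-deviation model (deterministic)
perfect_noise <- function(seed = 1, quantize = FALSE) {
  imu_noise(accel_sigma = 0, gyro_sigma = 0, accel_bias = c(0, 0, 0),
            accel_scale = c(1, 1, 1), gyro_bias = c(0, 0, 0),
            initial_tilt = 0, quantize = quantize, seed = seed)
}

# SI records for a stream at rest with gravity along +z
static_records <- function(n = 600, rate = 100) {
  tibble::tibble(t = (seq_len(n) - 1) / rate,
                 ax = 0, ay = 0, az = G0, gx = 0, gy = 0, gz = 0)
}

# accel-only table (ax, ay, az) from a 3-column matrix
accel_tbl <- function(m) {
  tibble::tibble(ax = m[, 1], ay = m[, 2], az = m[, 3])
}

# quasi-uniform unit directions plus antipodes (symmetric, well-conditioned)
sym_directions <- function(n = 12) {
  i <- seq_len(n)
  golden <- pi * (3 - sqrt(5))
  z <- 1 - (2 * i - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  d <- cbind(r * cos(golden * i), r * sin(golden * i), z)
  rbind(d, -d)
}

# fast small config for unit tests that do not need a 500-sample lead
small_config <- function(...) imu_config(static_window = 50, ...)
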