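#' Sphere-model accelerometer calibration
#'
#' In a static pose an ideal accelerometer reads a unit-norm gravity vector,
#' so static readings collected at many orientations lie on a sphere of radius
#' 1 g. A real sensor instead follows the deviation model `G = L (g + b)`,
#' with `G` the measured value (g units), `g` the true gravity direction, `L`
#' a diagonal per-axis scale matrix and `b` a bias vector: the readings lie on
#' an offset axis-aligned ellipsoid.
#'
#' `fit_accel_sphere()` estimates the model in two least-squares passes, each
#' linear in its parameters:
#' 1. with the scale assumed to be identity, the sphere constraint
#'    `|x - c|^2 = r^2` is linearized and the normal equations solved for the
#'    ellipsoid centre `c = L b`;
#' 2. with the centre removed, `sum_i (y_i / L_i)^2 = 1` is solved for the
#'    per-axis scales `L_i`.
#'
#' Because even a fitted model typically leaves the static norm slightly off
#' unity, [apply_calibration()] finishes with a per-stream normalization that
#' rescales the static-window mean norm to exactly 1 g.
#'
#' @param static_samples A data frame (or 3-column matrix) of static
#'   accelerometer readings in g units, columns `ax, ay, az`, taken at >= 4
#'   distinct orientations (>= 9 samples).
#' @return An object of class `accel_calibration`: list with `L` (length-3
#'   diagonal of the scale matrix), `b` (length-3 bias, g units), `rms_residual`
#'   (RMS deviation of calibrated sample norms from 1), and `n`.
#' @examples
#' pts <- simulate_calibration_set(imu_noise(accel_sigma = 0), n_orientations = 12)
#' fit_accel_sphere(pts)
#' @export
fit_accel_sphere <- function(static_samples) {
  m <- as.matrix(as.data.frame(static_samples)[, c("ax", "ay", "az")])
  storage.mode(m) <- "double"
  if (nrow(m) < 9) {
    abort("need at least 9 static samples to fit the sphere model",
          class = "instep_input_error")
  }
  # pass 1: |x - c|^2 = r^2  =>  2 x.c + (r^2 - |c|^2) = |x|^2, linear in (c, k)
  A <- cbind(2 * m, 1)
  y <- rowSums(m^2)
  qrA <- qr(A)
  if (qrA$rank < 4) {
    abort("degenerate calibration geometry: orientations are coplanar or too few",
          class = "instep_degenerate_error")
  }
  beta <- qr.coef(qrA, y)
  centre <- beta[1:3]
  # pass 2: centred samples satisfy sum((y_i / L_i)^2) = 1, linear in 1/L_i^2
  yc <- sweep(m, 2, centre)
  B <- yc^2
  qrB <- qr(B)
  if (qrB$rank < 3) {
    abort("degenerate calibration geometry: cannot resolve per-axis scales",
          class = "instep_degenerate_error")
  }
  invL2 <- qr.coef(qrB, rep(1, nrow(B)))
  if (any(invL2 <= 0)) {
    abort("degenerate calibration geometry: non-positive scale solution",
          class = "instep_degenerate_error")
  }
  L <- 1 / sqrt(invL2)
  b <- centre / L
  g_est <- sweep(sweep(m, 2, L, "/"), 2, b)   # L^-1 x - b
  rms <- sqrt(mean((sqrt(rowSums(g_est^2)) - 1)^2))
  structure(
    list(L = unname(L), b = unname(b), rms_residual = rms, n = nrow(m)),
    class = "accel_calibration"
  )
}

#' Identity calibration model
#'
#' @return An `accel_calibration` with unit scales and zero bias, for running
#'   the pipeline on already-calibrated data.
#' @export
identity_calibration <- function() {
  structure(list(L = rep(1, 3), b = rep(0, 3), rms_residual = 0, n = 0L),
            class = "accel_calibration")
}

#' @export
print.accel_calibration <- function(x, ...) {
  cat("<accel_calibration>\n")
  cat(sprintf("  scale L:  %s\n", paste(sprintf("%.5f", x$L), collapse = "  ")))
  cat(sprintf("  bias b:   %s  (g)\n", paste(sprintf("%+.5f", x$b), collapse = "  ")))
  cat(sprintf("  fit: n = %d, RMS norm residual = %.2e\n", x$n, x$rms_residual))
  invisible(x)
}

#' Apply an accelerometer calibration to an IMU stream
#'
#' Inverts the deviation model per sample (`g = L^-1 G - b`, computed in g
#' units) and then rescales the whole stream by the mean norm of its static
#' window so the static norm is exactly 1 g — the final normalization step of
#' the sphere calibration. Optionally the gyroscope bias, estimated as the
#' mean angular rate over the same static window, is subtracted; without it,
#' attitude drift would dominate the reconstruction.
#'
#' @param records SI records tibble from [read_imu_csv()] / [counts_to_si()].
#' @param model An `accel_calibration` from [fit_accel_sphere()].
#' @param config An [imu_config()] (supplies the static window length).
#' @param fix_gyro_bias Subtract the static-window mean gyro rate (default
#'   `TRUE`).
#' @return The records tibble with calibrated `ax..az` (and debiased
#'   `gx..gz`), plus an attribute `norm_factor`.
#' @export
apply_calibration <- function(records, model, config = imu_config(),
                              fix_gyro_bias = TRUE) {
  stopifnot(inherits(model, "accel_calibration"), inherits(config, "imu_config"))
  if (any(model$L <= 0) || any(!is.finite(model$L)) || any(!is.finite(model$b))) {
    abort("calibration model has non-positive or non-finite parameters",
          class = "instep_model_error")
  }
  n <- nrow(records)
  win <- min(config$static_window, n)
  a_g <- cbind(records$ax, records$ay, records$az) / STANDARD_GRAVITY
  g_est <- sweep(sweep(a_g, 2, model$L, "/"), 2, model$b)
  norm_factor <- mean(sqrt(rowSums(g_est[seq_len(win), , drop = FALSE]^2)))
  if (!is.finite(norm_factor) || norm_factor <= 0) {
    abort("static window has zero mean norm; cannot normalize",
          class = "instep_model_error")
  }
  g_est <- g_est / norm_factor
  out <- records
  out$ax <- g_est[, 1] * STANDARD_GRAVITY
  out$ay <- g_est[, 2] * STANDARD_GRAVITY
  out$az <- g_est[, 3] * STANDARD_GRAVITY
  if (fix_gyro_bias) {
    out$gx <- records$gx - mean(records$gx[seq_len(win)])
    out$gy <- records$gy - mean(records$gy[seq_len(win)])
    out$gz <- records$gz - mean(records$gz[seq_len(win)])
  }
  attr(out, "norm_factor") <- norm_factor
  out
}

#' Persist a calibration model as a key-value text file
#'
#' @param model An `accel_calibration`.
#' @param path File path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` the model.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "accel_calibration"))
  yaml::write_yaml(unclass(model), path, precision = 15)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("calibration file not found: '%s'", path), class = "instep_io_error")
  }
  vals <- yaml::read_yaml(path)
  need <- c("L", "b")
  if (!all(need %in% names(vals))) {
    abort("calibration file must contain keys 'L' and 'b'", class = "instep_parse_error")
  }
  structure(list(L = as.numeric(vals$L), b = as.numeric(vals$b),
                 rms_residual = as.numeric(vals$rms_residual %||% NA_real_),
                 n = as.integer(vals$n %||% 0L)),
            class = "accel_calibration")
}
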