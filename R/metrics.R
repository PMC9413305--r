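#' Kick-quality metrics from a kinematic track
#'
#' Extracts the three headline quantities of an instep kick from a
#' reconstructed (or ground-truth) track:
#' * `path_length` — total length of the 3D trajectory (sum of consecutive
#'   point distances), m;
#' * `max_speed` — maximum instantaneous foot speed, its sample index and the
#'   position where it occurs (ties resolved to the earliest sample), m/s;
#' * `backswing_height` — the apex of the pull-back: maximum height above the
#'   starting position over the samples *before* peak speed, m.
#'
#' @param track A `kick_track` tibble (columns `px..pz`, `vx..vz`), or any
#'   data frame with those columns.
#' @return For `kick_metrics()`, an object of class `kick_metrics` (named
#'   list with the fields above plus indices). The individual extractors
#'   return their quantity directly.
#' @examples
#' truth <- kick_truth()
#' kick_metrics(truth)
#' @export
kick_metrics <- function(track) {
  ms <- max_speed(track)
  bh <- tryCatch(backswing_height(track),
                 instep_phase_error = function(e) list(height = NA_real_, index = NA_integer_))
  structure(
    list(path_length = path_length(track),
         max_speed = ms$speed,
         max_speed_index = ms$index,
         max_speed_position = ms$position,
         backswing_height = bh$height,
         backswing_apex_index = bh$index),
    class = "kick_metrics"
  )
}

#' @export
print.kick_metrics <- function(x, ...) {
  cat("<kick_metrics>\n")
  cat(sprintf("  path length:      %.3f m\n", x$path_length))
  cat(sprintf("  max foot speed:   %.3f m/s (sample %d, at [%.2f, %.2f, %.2f] m)\n",
              x$max_speed, x$max_speed_index,
              x$max_speed_position[1], x$max_speed_position[2], x$max_speed_position[3]))
  cat(sprintf("  backswing apex:   %.3f m (sample %s)\n",
              x$backswing_height,
              ifelse(is.na(x$backswing_apex_index), "NA", x$backswing_apex_index)))
  invisible(x)
}

track_pos <- function(track) cbind(track$px, track$py, track$pz)
track_vel <- function(track) cbind(track$vx, track$vy, track$vz)

#' @rdname kick_metrics
#' @export
path_length <- function(track) {
  p <- track_pos(track)
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

#' @rdname kick_metrics
#' @export
max_speed <- function(track) {
  v <- track_vel(track)
  if (nrow(v) == 0) abort("track is empty", class = "instep_input_error")
  speed <- sqrt(rowSums(v^2))
  i <- which.max(speed)       # earliest index on ties
  list(speed = speed[i], index = i, position = track_pos(track)[i, ])
}

#' @rdname kick_metrics
#' @export
backswing_height <- function(track) {
  i_max <- max_speed(track)$index
  if (i_max <= 1) {
    abort("no samples precede the peak-speed sample: no backswing phase detected",
          class = "instep_phase_error")
  }
  z <- track$pz[seq_len(i_max - 1)] - track$pz[1]
  j <- which.max(z)
  list(height = z[j], index = j)
}

#' First sample of sustained motion
#'
#' The motion onset is the first sample whose gated acceleration norm is
#' nonzero for `min_run` consecutive samples — the point from which IMU and
#' reference trajectories are aligned.
#'
#' @param track A `kick_track` (gated `ax..az` columns).
#' @param min_run Required consecutive above-gate samples (default 3).
#' @return The sample index, or an error if the track never moves.
#' @export
motion_onset <- function(track, min_run = 3) {
  nz <- (track$ax != 0 | track$ay != 0 | track$az != 0)
  run <- 0L
  for (i in seq_along(nz)) {
    run <- if (nz[i]) run + 1L else 0L
    if (run >= min_run) return(i - min_run + 1L)
  }
  abort("no sustained motion found in track", class = "instep_phase_error")
}

#' Pair a track with a reference trajectory sampled at a different rate
#'
#' Linearly interpolates the track's positions (and velocities) at the
#' reference timestamps, truncated to the overlapping time span. Both inputs
#' are assumed to share a time origin (aligned at motion onset).
#'
#' @param track A `kick_track` with a `t` column.
#' @param ref Reference tibble with columns `t, x, y, z` and optionally
#'   `vx, vy, vz` (see [read_reference_csv()]). When velocities are absent
#'   they are computed by central finite differences of the positions.
#' @return A tibble of pairs: `t`, `imu_x..imu_z`, `ref_x..ref_z`,
#'   `imu_vx..`, `ref_vx..`.
#' @export
align_to_reference <- function(track, ref) {
  t0 <- max(min(track$t), min(ref$t))
  t1 <- min(max(track$t), max(ref$t))
  if (t1 <= t0) {
    abort("track and reference time spans do not overlap", class = "instep_alignment_error")
  }
  rt <- ref$t[ref$t >= t0 & ref$t <= t1]
  interp <- function(y) approx(track$t, y, xout = rt, rule = 2)$y
  rsel <- ref[ref$t >= t0 & ref$t <= t1, ]
  if (!all(c("vx", "vy", "vz") %in% names(rsel))) {
    dv <- function(y) {
      n <- length(y)
      if (n < 2) return(rep(0, n))
      c(diff(y[1:2]) / diff(rsel$t[1:2]),
        if (n > 2) (y[3:n] - y[1:(n - 2)]) / (rsel$t[3:n] - rsel$t[1:(n - 2)]) else NULL,
        diff(y[(n - 1):n]) / diff(rsel$t[(n - 1):n]))
    }
    rsel$vx <- dv(rsel$x); rsel$vy <- dv(rsel$y); rsel$vz <- dv(rsel$z)
  }
  tibble(
    t = rt,
    imu_x = interp(track$px), imu_y = interp(track$py), imu_z = interp(track$pz),
    ref_x = rsel$x, ref_y = rsel$y, ref_z = rsel$z,
    imu_vx = interp(track$vx), imu_vy = interp(track$vy), imu_vz = interp(track$vz),
    ref_vx = rsel$vx, ref_vy = rsel$vy, ref_vz = rsel$vz
  )
}

#' Trajectory and velocity RMSE over paired samples
#'
#' Position RMSE is computed on the full 3D point-to-point distances.
#' Velocity RMSE is reported both as the 3D analogue and along the principal
#' (kick) direction — the first principal component of the reference
#' positions, sign-aligned with the net displacement.
#'
#' @param pairs A pairs tibble from [align_to_reference()].
#' @return A list: `position_rmse` (m), `velocity_rmse` (m/s, 3D),
#'   `velocity_rmse_kick_direction` (m/s), `kick_direction` (unit 3-vector),
#'   `n`.
#' @export
trajectory_rmse <- function(pairs) {
  if (nrow(pairs) < 1) abort("empty pairing", class = "instep_input_error")
  dp <- cbind(pairs$imu_x - pairs$ref_x, pairs$imu_y - pairs$ref_y, pairs$imu_z - pairs$ref_z)
  dvel <- cbind(pairs$imu_vx - pairs$ref_vx, pairs$imu_vy - pairs$ref_vy, pairs$imu_vz - pairs$ref_vz)
  refp <- cbind(pairs$ref_x, pairs$ref_y, pairs$ref_z)
  dir <- kick_direction(refp)
  list(position_rmse = sqrt(mean(rowSums(dp^2))),
       velocity_rmse = sqrt(mean(rowSums(dvel^2))),
       velocity_rmse_kick_direction = sqrt(mean((dvel %*% dir)^2)),
       kick_direction = dir,
       n = nrow(pairs))
}

kick_direction <- function(pos) {
  disp <- pos[nrow(pos), ] - pos[1, ]
  if (nrow(pos) < 3 || all(apply(pos, 2, sd) == 0)) {
    if (sum(disp^2) == 0) return(c(0, 1, 0))
    return(disp / sqrt(sum(disp^2)))
  }
  pc1 <- prcomp(pos, center = TRUE, scale. = FALSE)$rotation[, 1]
  if (sum(pc1 * disp) < 0) pc1 <- -pc1
  unname(pc1)
}

#' Bland-Altman limits-of-agreement analysis of paired positions
#'
#' For each axis, the per-pair difference `d = imu - ref` is summarized by its
#' mean (the bias) and the 95% limits of agreement `bias +/- 1.96 sd(d)`,
#' together with the fraction of points falling outside those limits. A
#' pooled count across axes is also reported.
#'
#' @param pairs A pairs tibble from [align_to_reference()], or any data frame
#'   with `imu_x..imu_z` and `ref_x..ref_z` columns.
#' @return An object of class `bland_altman`: list with `stats` (per-axis
#'   tibble: `axis, n, bias, sd, lower, upper, n_outside, frac_outside`) and
#'   pooled `n_outside` / `frac_outside`.
#' @export
bland_altman <- function(pairs) {
  if (nrow(pairs) < 3) abort("Bland-Altman needs at least 3 pairs", class = "instep_input_error")
  one_axis <- function(axis) {
    d <- pairs[[paste0("imu_", axis)]] - pairs[[paste0("ref_", axis)]]
    m <- (pairs[[paste0("imu_", axis)]] + pairs[[paste0("ref_", axis)]]) / 2
    bias <- mean(d); s <- sd(d)
    lower <- bias - 1.96 * s; upper <- bias + 1.96 * s
    out <- sum(d < lower | d > upper)
    tibble(axis = axis, n = length(d), bias = bias, sd = s,
           lower = lower, upper = upper,
           n_outside = out, frac_outside = out / length(d))
  }
  stats <- dplyr::bind_rows(lapply(c("x", "y", "z"), one_axis))
  structure(list(stats = stats,
                 n_outside = sum(stats$n_outside),
                 n_total = sum(stats$n),
                 frac_outside = sum(stats$n_outside) / sum(stats$n),
                 pairs = pairs),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("<bland_altman>\n")
  print(as.data.frame(x$stats), row.names = FALSE, digits = 4)
  cat(sprintf("  pooled: %d of %d points (%.2f%%) outside the 95%% limits\n",
              x$n_outside, x$n_total, 100 * x$frac_outside))
  invisible(x)
}

#' Full agreement report of a track against a reference trajectory
#'
#' Crops both series to the motion span (from the track's [motion_onset()] to
#' its last moving sample), pairs them with [align_to_reference()], and
#' reports position/velocity RMSE plus the per-axis Bland-Altman analysis.
#'
#' @param track A `kick_track`.
#' @param ref Reference tibble (`t, x, y, z`, optional velocities), sharing
#'   the track's time base.
#' @param span `"motion"` (default) restricts the comparison to the moving
#'   part of the track; `"overlap"` uses the full overlapping time span.
#' @return An object of class `kick_agreement`: RMSE fields of
#'   [trajectory_rmse()] plus `bland_altman` and `n_pairs`.
#' @export
compare_to_reference <- function(track, ref, span = c("motion", "overlap")) {
  span <- match.arg(span)
  if (span == "motion") {
    moving <- which(track$ax != 0 | track$ay != 0 | track$az != 0)
    if (!length(moving)) {
      abort("track never moves; cannot define a motion span", class = "instep_phase_error")
    }
    tr <- track[seq(motion_onset(track), max(moving)), ]
  } else {
    tr <- track
  }
  pairs <- align_to_reference(tr, ref)
  rmse <- trajectory_rmse(pairs)
  structure(c(rmse, list(bland_altman = bland_altman(pairs), n_pairs = nrow(pairs))),
            class = "kick_agreement")
}

#' @export
print.kick_agreement <- function(x, ...) {
  cat("<kick_agreement>\n")
  cat(sprintf("  position RMSE:              %.4f m   (n = %d pairs)\n", x$position_rmse, x$n_pairs))
  cat(sprintf("  velocity RMSE (3D):         %.4f m/s\n", x$velocity_rmse))
  cat(sprintf("  velocity RMSE (kick dir.):  %.4f m/s\n", x$velocity_rmse_kick_direction))
  cat(sprintf("  kick direction:             [%.2f, %.2f, %.2f]\n",
              x$kick_direction[1], x$kick_direction[2], x$kick_direction[3]))
  cat(sprintf("  Bland-Altman: %d of %d points outside 95%% limits (%.2f%%)\n",
              x$bland_altman$n_outside, x$bland_altman$n_total,
              100 * x$bland_altman$frac_outside))
  invisible(x)
}
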