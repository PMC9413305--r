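track_from_pos <- function(p, dt = 0.01, v = NULL) {
  n <- nrow(p)
  if (is.null(v)) v <- rbind(0, diff(p) / dt)
  tibble::tibble(t = (seq_len(n) - 1) * dt,
                 ax = 0, ay = 0, az = 0,
                 vx = v[, 1], vy = v[, 2], vz = v[, 3],
                 px = p[, 1], py = p[, 2], pz = p[, 3],
                 stationary = FALSE)
}

test_that("path length sums chords and approximates arc length", {
  expect_equal(path_length(track_from_pos(matrix(0, 10, 3))), 0)
  line <- cbind(seq(0, 1, length.out = 11), 0, 0)
  expect_equal(path_length(track_from_pos(line)), 1)
  th <- seq(0, pi, by = pi / 180)
  semi <- cbind(cos(th), sin(th), 0)
  expect_equal(path_length(track_from_pos(semi)), pi, tolerance = 1e-4)
})

test_that("path length is invariant under rigid rotation", {
  withr::local_seed(10)
  p <- apply(matrix(rnorm(60, sd = 0.1), 20, 3), 2, cumsum)
  R <- quat_to_matrix(quat_normalize(rnorm(4)))
  expect_equal(path_length(track_from_pos(p %*% t(R))),
               path_length(track_from_pos(p)), tolerance = 1e-12)
})

test_that("max speed returns the earliest maximum with its position", {
  zero <- track_from_pos(matrix(0, 5, 3))
  ms <- max_speed(zero)
  expect_equal(ms$speed, 0); expect_equal(ms$index, 1)
  expect_equal(ms$position, c(0, 0, 0))
  t <- seq(0, 1, by = 0.01)
  ramp <- track_from_pos(cbind(t^2 / 2, 0, 0), v = cbind(t, 0, 0))
  expect_equal(max_speed(ramp)$index, length(t))     # growing speed peaks last
  tie <- track_from_pos(matrix(0, 6, 3), v = cbind(c(0, 2, 1, 2, 0, 0), 0, 0))
  expect_equal(max_speed(tie)$index, 2)              # earliest of the tied maxima
})

test_that("max speed of a concatenation is the max over the parts", {
  withr::local_seed(11)
  v1 <- matrix(rnorm(30), 10, 3); v2 <- matrix(rnorm(30), 10, 3)
  t1 <- track_from_pos(matrix(0, 10, 3), v = v1)
  t2 <- track_from_pos(matrix(0, 10, 3), v = v2)
  t12 <- track_from_pos(matrix(0, 20, 3), v = rbind(v1, v2))
  expect_equal(max_speed(t12)$speed, max(max_speed(t1)$speed, max_speed(t2)$speed))
})

test_that("backswing apex is the pre-peak height maximum relative to the start", {
  # forward-only motion whose speed peaks at the very first sample: no backswing
  mono <- track_from_pos(matrix(0, 5, 3), v = cbind(c(5, 1, 1, 1, 1), 0, 0))
  expect_error(backswing_height(mono), class = "instep_phase_error")
  # arc rising to 0.756 m then sweeping down into the fastest point
  t <- seq(0, 1, by = 0.01)
  z <- 0.756 * sin(pi * t)           # apex 0.756 at t = 0.5
  arc <- track_from_pos(cbind(0, t, z),
                        v = rbind(matrix(0, 99, 3),          # slow swing ...
                                  matrix(c(8, 0, 0), 2, 3, byrow = TRUE)))  # speed peak at the end
  bh <- backswing_height(arc)
  expect_equal(bh$height, 0.756, tolerance = 1e-6)
  expect_equal(bh$index, 51)
  # flat track then kick: apex is non-negative
  flat <- track_from_pos(cbind(c(rep(0, 10), seq(0, 1, length.out = 10)), 0, 0),
                         v = cbind(c(rep(0, 10), rep(1, 10)), 0, 0))
  expect_gte(backswing_height(flat)$height, 0)
})

test_that("kick metrics bundle tidies into tibbles", {
  truth <- kick_truth()
  km <- kick_metrics(truth)
  expect_equal(km$max_speed, 7.47, tolerance = 1e-9)
  expect_equal(km$backswing_height, 0.756, tolerance = 1e-9)
  td <- tidy(km)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$value[td$metric == "path_length"], 3.63, tolerance = 1e-6)
  gl <- glance(km)
  expect_equal(nrow(gl), 1)
  expect_true(gl$max_speed_index < nrow(truth))
})

test_that("resampling to the reference handles equal, coarser and finer rates", {
  t <- seq(0, 1, by = 0.01)
  trk <- track_from_pos(cbind(t, 2 * t, -t), v = cbind(rep(1, 101), 2, -1))
  ref_same <- tibble::tibble(t = t, x = t, y = 2 * t, z = -t)
  pairs <- align_to_reference(trk, ref_same)
  expect_equal(pairs$imu_x, pairs$ref_x, tolerance = 1e-12)
  expect_equal(nrow(pairs), 101)
  ref_50 <- ref_same[seq(1, 101, by = 2), ]
  expect_equal(nrow(align_to_reference(trk, ref_50)), 51)
  # 240 Hz reference on a linear trajectory: interpolation is exact
  t240 <- seq(0, 1, by = 1 / 240)
  ref_240 <- tibble::tibble(t = t240, x = t240, y = 2 * t240, z = -t240)
  p240 <- align_to_reference(trk, ref_240)
  expect_equal(p240$imu_y, p240$ref_y, tolerance = 1e-12)
  expect_error(align_to_reference(trk, dplyr::mutate(ref_same, t = t + 10)),
               class = "instep_alignment_error")
})

test_that("trajectory RMSE matches closed forms", {
  t <- seq(0, 1, by = 0.01)
  trk <- track_from_pos(cbind(t, 0, 0), v = cbind(rep(1, 101), 0, 0))
  ref <- tibble::tibble(t = t, x = t, y = 0, z = 0, vx = 1, vy = 0, vz = 0)
  pairs <- align_to_reference(trk, ref)
  r0 <- trajectory_rmse(pairs)
  expect_equal(r0$position_rmse, 0)
  expect_equal(r0$velocity_rmse, 0)
  pairs_off <- dplyr::mutate(pairs, imu_x = imu_x + 0.1)
  expect_equal(trajectory_rmse(pairs_off)$position_rmse, 0.1, tolerance = 1e-12)
  # isotropic gaussian perturbation: 3D RMSE concentrates near sigma * sqrt(3)
  withr::local_seed(12)
  n <- 20000
  tt <- seq(0, 1, length.out = n)
  big <- tibble::tibble(t = tt,
                        imu_x = rnorm(n, sd = 0.05), imu_y = 1 + rnorm(n, sd = 0.05),
                        imu_z = rnorm(n, sd = 0.05),
                        ref_x = 0, ref_y = 1, ref_z = 0,
                        imu_vx = 0, imu_vy = 0, imu_vz = 0,
                        ref_vx = 0, ref_vy = 0, ref_vz = 0)
  expect_equal(trajectory_rmse(big)$position_rmse, 0.05 * sqrt(3), tolerance = 0.02)
})

test_that("Bland-Altman recovers bias and the gaussian outside fraction", {
  t <- seq(0, 1, by = 0.01)
  base <- tibble::tibble(t = t, imu_x = t, imu_y = t, imu_z = t,
                         ref_x = t, ref_y = t, ref_z = t,
                         imu_vx = 0, imu_vy = 0, imu_vz = 0,
                         ref_vx = 0, ref_vy = 0, ref_vz = 0)
  ba0 <- bland_altman(base)
  expect_equal(ba0$stats$bias, rep(0, 3))
  expect_equal(ba0$n_outside, 0)        # zero variance: limits collapse, none outside
  ba_c <- bland_altman(dplyr::mutate(base, imu_x = imu_x + 0.02))
  expect_equal(ba_c$stats$bias[ba_c$stats$axis == "x"], 0.02, tolerance = 1e-12)
  withr::local_seed(13)
  n <- 50000
  noisy <- tibble::tibble(t = seq_len(n), imu_x = rnorm(n), imu_y = rnorm(n), imu_z = rnorm(n),
                          ref_x = 0, ref_y = 0, ref_z = 0,
                          imu_vx = 0, imu_vy = 0, imu_vz = 0,
                          ref_vx = 0, ref_vy = 0, ref_vz = 0)
  ban <- bland_altman(noisy)
  expect_equal(ban$frac_outside, 0.05, tolerance = 0.005)
  expect_error(bland_altman(base[1:2, ]), class = "instep_input_error")
})

test_that("motion onset finds the first sustained above-gate sample", {
  acc <- rbind(matrix(0, 30, 3), matrix(c(1, 0, 0), 10, 3, byrow = TRUE))
  trk <- integrate_track(accel_tbl(acc), imu_config())
  expect_equal(motion_onset(trk), 31)
  expect_error(motion_onset(integrate_track(accel_tbl(matrix(0, 20, 3)), imu_config())),
               class = "instep_phase_error")
})
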