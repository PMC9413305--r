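test_that("static offset is the component-wise mean of the window", {
  acc <- accel_tbl(matrix(rep(c(0, 0, G0), each = 600), ncol = 3))
  off <- static_offset(acc, 500)
  expect_equal(off$offset, c(0, 0, G0))
  expect_equal(static_offset(accel_tbl(rbind(c(1, 2, 9.6), c(4, 5, 6))), 1)$offset,
               c(1, 2, 9.6))
  expect_error(static_offset(acc[1:100, ], 500), class = "instep_input_error")
})

test_that("static offset under noise obeys the CLT bound", {
  withr::local_seed(9)
  sigma <- 0.01
  m <- matrix(rnorm(500 * 3, sd = sigma), ncol = 3)
  m[, 3] <- m[, 3] + G0
  off <- static_offset(accel_tbl(m), 500)
  expect_lt(max(abs(off$offset - c(0, 0, G0))), 3 * sigma / sqrt(500))
})

test_that("a non-static window triggers a warning", {
  acc <- accel_tbl(matrix(rep(c(0, 0, 0.5 * G0), each = 100), ncol = 3))
  expect_warning(static_offset(acc, 100), "static")
})

test_that("gravity compensation subtracts the offset everywhere", {
  off <- static_offset(accel_tbl(matrix(rep(c(0, 0, 3), each = 10), ncol = 3,
                                        byrow = FALSE)), 10) |> suppressWarnings()
  out <- remove_gravity(accel_tbl(rbind(c(1, 2, 3), c(0, 0, 3))), off)
  expect_equal(unlist(out[1, ], use.names = FALSE), c(1, 2, 0))
  expect_equal(unlist(out[2, ], use.names = FALSE), c(0, 0, 0))
})

test_that("tilt correction recovers pure roll and levels the offset", {
  off0 <- structure(list(offset = c(0, 0, G0), window = 500L), class = "static_offset")
  t0 <- tilt_from_offset(off0)
  expect_equal(t0$roll, 0); expect_equal(t0$pitch, 0)
  expect_equal(t0$R, diag(3))
  off10 <- structure(list(offset = c(0, G0 * sin(10 * pi / 180), G0 * cos(10 * pi / 180)),
                          window = 500L), class = "static_offset")
  t10 <- tilt_from_offset(off10)
  expect_equal(t10$roll * 180 / pi, 10, tolerance = 1e-10)
  lev <- as.numeric(t10$R %*% off10$offset)
  expect_equal(lev[1:2], c(0, 0), tolerance = 1e-12)
  expect_equal(lev[3], G0, tolerance = 1e-12)
})

test_that("tilt correction aligns arbitrary small tilts exactly with +z", {
  withr::local_seed(4)
  for (rep in 1:50) {
    r <- runif(1, -15, 15) * pi / 180
    p <- runif(1, -15, 15) * pi / 180
    Rx <- matrix(c(1, 0, 0, 0, cos(r), -sin(r), 0, sin(r), cos(r)), 3, byrow = TRUE)
    Ry <- matrix(c(cos(p), 0, sin(p), 0, 1, 0, -sin(p), 0, cos(p)), 3, byrow = TRUE)
    o <- as.numeric(Ry %*% Rx %*% c(0, 0, G0))
    tc <- tilt_from_offset(structure(list(offset = o, window = 1L), class = "static_offset"))
    lev <- as.numeric(tc$R %*% o)
    expect_lt(max(abs(lev[1:2])), 1e-9 * G0)
    expect_true(abs(det(tc$R) - 1) < 1e-12)
    expect_equal(crossprod(tc$R), diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("a sensor on its side is a degenerate attitude", {
  off <- structure(list(offset = c(G0, 0, 0), window = 500L), class = "static_offset")
  expect_error(tilt_from_offset(off), class = "instep_degenerate_error")
})

test_that("apply_tilt rotates samples and preserves norms", {
  off45 <- structure(list(offset = c(0, G0 / sqrt(2), G0 / sqrt(2)), window = 1L),
                     class = "static_offset")
  tc <- tilt_from_offset(off45)   # roll 45 degrees
  out <- apply_tilt(accel_tbl(rbind(c(0, 1, 0), c(1, 0, 0))), tc)
  expect_equal(unlist(out[1, ], use.names = FALSE),
               c(0, cos(pi / 4), sin(pi / 4)), tolerance = 1e-12)
  expect_equal(unlist(out[2, ], use.names = FALSE), c(1, 0, 0))
  withr::local_seed(6)
  m <- matrix(rnorm(60), ncol = 3)
  rot <- apply_tilt(accel_tbl(m), tc)
  expect_equal(sqrt(rot$ax^2 + rot$ay^2 + rot$az^2), sqrt(rowSums(m^2)), tolerance = 1e-12)
})

test_that("acceleration gating zeroes sub-threshold samples and only those", {
  acc <- accel_tbl(rbind(c(0.1, 0, 0), c(5, 0, 0), c(0.2, 0.2, 0.2), c(0, 0.4, 0)))
  out <- gate_accel(acc, 0.392)
  expect_equal(out$ax, c(0, 5, 0, 0))
  expect_equal(out$ay, c(0, 0, 0, 0.4))
  # gate 0 is the identity
  expect_equal(gate_accel(acc, 0), acc)
  # gating never increases any sample's magnitude
  expect_true(all(sqrt(out$ax^2 + out$ay^2 + out$az^2) <=
                  sqrt(acc$ax^2 + acc$ay^2 + acc$az^2)))
})

test_that("trapezoidal integration is exact for constant and linear acceleration", {
  cfg <- imu_config(zupt_run_length = 200, static_window = 200)  # disable ZUPT here
  # constant 1 m/s^2 for 1 s at 100 Hz
  n <- 101
  acc <- accel_tbl(cbind(rep(1, n), 0, 0))
  trk <- integrate_track(acc, cfg)
  expect_equal(trk$vx[n], 1, tolerance = 1e-12)
  # linear a(t) = 2 t: v(1) = 1 exactly under the trapezoid rule
  t <- (seq_len(n) - 1) / 100
  trk2 <- integrate_track(accel_tbl(cbind(2 * t, 0, 0)), cfg)
  expect_equal(trk2$vx[n], 1, tolerance = 1e-12)
  # and the position integral of the constant case: p = v t^2 / 2 + O(dt^2)
  expect_equal(trk$px[n], 0.5, tolerance = 1e-4)
  expect_equal(trk$vx[1], 0)
  expect_equal(trk$px[1], 0)
})

test_that("fifteen consecutive gated-zero samples reset velocity to zero for good", {
  cfg <- imu_config()
  acc <- accel_tbl(cbind(c(rep(2, 30), rep(0, 40)), 0, 0))
  trk <- integrate_track(acc, cfg)
  expect_gt(trk$vx[30], 0.5)
  # before the ZUPT run completes the velocity persists; afterwards it is 0
  expect_false(trk$stationary[30 + 14])
  expect_true(all(trk$stationary[(30 + 15):70]))
  expect_true(all(trk$vx[(30 + 15):70] == 0))
  expect_true(all(diff(trk$px[(30 + 15):70]) == 0))   # position frozen
  # stationary flag implies exactly zero velocity
  expect_true(all((trk$vx[trk$stationary] == 0) & (trk$vy[trk$stationary] == 0)))
})

test_that("velocity stays zero until an above-gate acceleration arrives", {
  cfg <- imu_config()
  acc <- accel_tbl(cbind(c(rep(0, 20), rep(1, 5), rep(0, 30), rep(1, 5)), 0, 0))
  trk <- integrate_track(acc, cfg)
  still <- 25 + 15
  expect_true(all(trk$vx[still:55] == 0))
  expect_gt(trk$vx[57], 0)   # motion resumes once gated acceleration returns
})

test_that("a purely static stream reconstructs to the origin", {
  rec <- static_records(600)
  trk <- reconstruct_track(rec, config = imu_config())
  expect_lt(max(sqrt(trk$px^2 + trk$py^2 + trk$pz^2)), 1e-6)
  expect_true(all(trk$vx == 0))
})

test_that("a too-short stream is rejected", {
  expect_error(reconstruct_track(static_records(100), config = imu_config()),
               class = "instep_input_error")
})

test_that("zero-noise round trip reconstructs the kick to centimetre accuracy", {
  truth <- kick_truth()
  rec <- simulate_imu(truth, perfect_noise(), imu_config())
  trk <- reconstruct_track(rec, config = imu_config())
  err <- sqrt((trk$px - truth$px)^2 + (trk$py - truth$py)^2 + (trk$pz - truth$pz)^2)
  expect_lt(max(err), 0.01)
  agr <- compare_to_reference(trk, as_reference(truth))
  expect_lt(agr$position_rmse, 0.01)
  # after the landing ZUPT the foot is at rest again
  expect_equal(tail(trk$vx, 1), 0)
  expect_true(tail(trk$stationary, 1))
})

test_that("with a tilted mount the reconstructed world frame is still level", {
  noise <- perfect_noise(seed = 21)
  noise$initial_tilt <- 10 * pi / 180
  truth <- kick_truth()
  rec <- simulate_imu(truth, noise, imu_config())
  trk <- reconstruct_track(rec, config = imu_config())
  err <- sqrt((trk$px - truth$px)^2 + (trk$py - truth$py)^2 + (trk$pz - truth$pz)^2)
  expect_lt(max(err), 0.02)
})

test_that("reconstruction error shrinks when the sampling rate doubles", {
  run_err <- function(rate) {
    truth <- kick_truth(dt = 1 / rate)
    cfg <- imu_config(sample_rate_hz = rate)
    rec <- simulate_imu(truth, perfect_noise(), cfg)
    trk <- reconstruct_track(rec, config = cfg)
    sqrt(mean((trk$px - truth$px)^2 + (trk$py - truth$py)^2 + (trk$pz - truth$pz)^2))
  }
  e100 <- run_err(100); e200 <- run_err(200)
  expect_lt(e200, e100)
})
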