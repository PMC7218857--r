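test_that("gyro offset is the mean scaled static value per axis", {
  zeros <- matrix(0, 100, 3)
  expect_equal(estimate_gyro_offset(zeros), c(0, 0, 0))

  const <- cbind(rep(100, 100), 0, 0)
  expect_equal(estimate_gyro_offset(const), c(6, 0, 0))
})

test_that("offset of zero-mean noise shrinks with the CLT rate", {
  set.seed(11)
  n <- 1000
  sd_counts <- 10  # 0.6 deg/s scaled
  noise <- matrix(rnorm(3 * n, sd = sd_counts), n, 3)
  off <- estimate_gyro_offset(noise, check_static = FALSE)
  expect_true(all(abs(off) <= 4 * sd_counts * 0.06 / sqrt(n)))
})

test_that("gyro calibration subtracts the offset after scaling", {
  st <- imu_calibration(gyro_offset = c(6, -3, 0), acc_norm = 4166)
  expect_equal(calibrate_gyro(c(100, -50, 0), st), c(0, 0, 0))
  st0 <- imu_calibration(gyro_offset = c(0, 0, 0), acc_norm = 4166)
  expect_equal(calibrate_gyro(c(1000, 0, 0), st0), c(60, 0, 0))
})

test_that("accelerometer norm follows the Pythagorean mean", {
  w <- matrix(rep(c(0, 0, 4096), each = 50), 50, 3)
  expect_equal(estimate_acc_norm(w), 4096)
  k <- 700
  w2 <- matrix(rep(c(3, 4, 0) * k, each = 50), 50, 3)
  expect_equal(estimate_acc_norm(w2), 5 * k)

  set.seed(12)
  noisy <- sweep(matrix(rnorm(3000, sd = 20), 1000, 3), 2, c(0, 0, 4096), "+")
  expect_equal(estimate_acc_norm(noisy), 4096, tolerance = 0.01)
  expect_error(estimate_acc_norm(matrix(0, 50, 3)), "fault")
})

test_that("accelerometer calibration maps the norm to unit gravity", {
  st <- imu_calibration(acc_norm = 4166)
  expect_equal(calibrate_acc(c(0, 0, 4166), st), c(0, 0, 1))
  expect_equal(calibrate_acc(c(0, 0, -4166), st), c(0, 0, -1))
  # a noiseless 30-degree tilt preserves the unit norm exactly
  tilted <- 4166 * c(sin(pi / 6), 0, cos(pi / 6))
  expect_equal(sqrt(sum(calibrate_acc(tilted, st)^2)), 1, tolerance = 1e-9)
  expect_error(calibrate_acc(c(1, 1, 1), imu_calibration(acc_norm = 0)), "norm")
})

test_that("simulated static bias is removed to under 0.1 deg/s", {
  p0 <- standing_profile(n_cycles = 3)
  segs <- joints_to_segments(generate_joint_trajectories(p0, fs = 100))
  tr <- synthesize_imu(segs, sensor_params(fs = 100, gyro_noise_sd = 0.5,
                                           acc_noise_sd = 0.01,
                                           gyro_bias = c(7, -12, 3), seed = 21))
  cal <- calibrate_trial(tr)
  for (id in names(cal)) {
    rows <- tr[tr$sensor_id == id, ]
    g <- calibrate_gyro(as.matrix(rows[, c("gx", "gy", "gz")]), cal[[id]])
    expect_true(all(abs(colMeans(g)) <= 0.1))
  }
})

test_that("non-static calibration windows are rejected", {
  set.seed(13)
  moving <- cbind(2000 * sin(seq(0, 10, length.out = 500)), 0, 0)
  expect_error(estimate_gyro_offset(moving), "not static")
  acc_moving <- cbind(4000 * seq(0.2, 1.8, length.out = 500), 0, 100)
  expect_error(estimate_acc_norm(acc_moving), "not static")
})

test_that("calibration states are independent across trials", {
  p0 <- standing_profile(n_cycles = 2)
  segs <- joints_to_segments(generate_joint_trajectories(p0, fs = 100))
  tr_a <- synthesize_imu(segs, sensor_params(fs = 100, gyro_noise_sd = 0,
                                             acc_noise_sd = 0,
                                             gyro_bias = c(5, 0, 0), seed = 1))
  tr_b <- synthesize_imu(segs, sensor_params(fs = 100, gyro_noise_sd = 0,
                                             acc_noise_sd = 0,
                                             gyro_bias = c(0, 9, 0), seed = 1))
  cal_a1 <- calibrate_trial(tr_a)
  cal_b <- calibrate_trial(tr_b)   # interleaved: must not contaminate
  cal_a2 <- calibrate_trial(tr_a)
  expect_identical(cal_a1, cal_a2)
  expect_equal(cal_b[["trunk_c"]]$gyro_offset[2], 9, tolerance = 0.06)
})
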