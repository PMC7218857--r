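test_that("zero-amplitude profiles give constant joint angles", {
  zero <- list(offset = 0, amp = 0, phase = 0)
  five <- list(offset = 5, amp = 0, phase = 0)
  p <- gait_profile(harmonics = list(hip = zero, knee = five, ankle = zero),
                    n_cycles = 2)
  js <- generate_joint_trajectories(p, fs = 50)
  expect_true(all(js$hip == 0))
  expect_true(all(js$knee == 5))
  expect_true(all(js$ankle == 0))
})

test_that("a single hip harmonic spans exactly twice its amplitude", {
  # cadence 120 -> 1 s stride of 100 samples, so samples land on the peaks
  zero <- list(offset = 0, amp = 0, phase = 0)
  p <- gait_profile(cadence = 120, n_cycles = 2,
                    harmonics = list(hip = list(offset = 0, amp = 15, phase = 0),
                                     knee = zero, ankle = zero))
  js <- generate_joint_trajectories(p, fs = 100)
  expect_equal(diff(range(js$hip[, "right"])), 30, tolerance = 1e-12)
})

test_that("trajectory generation is deterministic and validates inputs", {
  p <- gait_profile(n_cycles = 3)
  a <- generate_joint_trajectories(p, fs = 100)
  b <- generate_joint_trajectories(p, fs = 100)
  expect_identical(a, b)
  expect_error(gait_profile(cadence = 0), "cadence")
  expect_error(gait_profile(n_cycles = 0), "n_cycles")
})

test_that("knee stance minimum is at zero degrees for flat walking", {
  js <- generate_joint_trajectories(gait_profile(n_cycles = 4), fs = 100)
  expect_gte(min(js$knee), -1e-9)
  expect_lt(min(js$knee), 0.5)
})

test_that("joints_to_segments matches the neutral-stance arithmetic", {
  js <- joint_series(hip = rep(0, 5), knee = rep(0, 5), ankle = rep(0, 5), fs = 100)
  seg <- joints_to_segments(js, trunk = 90)
  expect_equal(unname(seg$thigh[1, 1]), -90)
  expect_equal(unname(seg$shank[1, 1]), -90)
  expect_equal(unname(seg$foot[1, 1]), 0)

  js2 <- joint_series(hip = rep(0, 5), knee = rep(40, 5), ankle = rep(0, 5), fs = 100)
  seg2 <- joints_to_segments(js2, trunk = 90)
  expect_equal(unname(seg2$shank[1, 1]), -130)
})

test_that("joint -> segment -> joint round trip is the identity", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    js <- joint_series(hip = matrix(runif(2 * n, -40, 60), ncol = 2,
                                    dimnames = list(NULL, c("left", "right"))),
                       knee = matrix(runif(2 * n, 0, 70), ncol = 2,
                                     dimnames = list(NULL, c("left", "right"))),
                       ankle = matrix(runif(2 * n, -30, 30), ncol = 2,
                                      dimnames = list(NULL, c("left", "right"))),
                       fs = 100)
    trunk <- runif(n, 70, 110)
    back <- joint_angles(joints_to_segments(js, trunk))
    expect_lt(max(abs(back$hip - js$hip)), 1e-9)
    expect_lt(max(abs(back$knee - js$knee)), 1e-9)
    expect_lt(max(abs(back$ankle - js$ankle)), 1e-9)
  }
})

test_that("static synthesis yields zero gyro counts and unit gravity", {
  fx <- noiseless_trial(n_cycles = 2)
  p0 <- standing_profile(n_cycles = 2)
  js <- generate_joint_trajectories(p0, fs = 100)
  segs <- joints_to_segments(js)
  tr <- synthesize_imu(segs, sensor_params(fs = 100, gyro_noise_sd = 0,
                                           acc_noise_sd = 0, seed = 1))
  expect_true(all(tr$gx == 0) && all(tr$gy == 0) && all(tr$gz == 0))
  acc_g <- sqrt(tr$ax^2 + tr$ay^2 + tr$az^2) * 0.00024
  expect_true(all(abs(acc_g - 1) < 0.001))  # quantization only
})

test_that("gyro bias passes through to the scaled static signal", {
  p0 <- standing_profile(n_cycles = 2)
  segs <- joints_to_segments(generate_joint_trajectories(p0, fs = 100))
  tr <- synthesize_imu(segs, sensor_params(fs = 100, gyro_noise_sd = 0,
                                           acc_noise_sd = 0,
                                           gyro_bias = c(10, 0, 0), seed = 1))
  expect_equal(mean(tr$gx) * 0.06, 10, tolerance = 0.06)
  expect_equal(mean(tr$gz) * 0.06, 0, tolerance = 0.06)
})

test_that("noiseless sinusoid gives the analytic angular rate", {
  fs <- 100
  t <- seq(0, 4, by = 1 / fs)
  theta <- 10 * sin(2 * pi * t)
  segs <- segment_series(trunk = rep(90, length(t)),
                         thigh = theta - 90, shank = theta - 90,
                         foot = theta, fs = fs, t = t)
  tr <- synthesize_imu(segs, sensor_params(fs = fs, gyro_noise_sd = 0,
                                           acc_noise_sd = 0, seed = 1),
                       calib_window = 0)
  rows <- tr[tr$sensor_id == "foot_r", ]
  w <- rows$gy * 0.06
  # backward difference approximates the derivative at the midpoint
  mid <- t[-1] - 1 / (2 * fs)
  expect_lt(max(abs(w[-1] - 20 * pi * cos(2 * pi * mid))),
            0.1)  # discretization + one-count quantization
})

test_that("same seed gives bit-identical trials", {
  fx1 <- noiseless_trial(seed = 7, gyro_noise_sd = 0.5, acc_noise_sd = 0.01)
  fx2 <- noiseless_trial(seed = 7, gyro_noise_sd = 0.5, acc_noise_sd = 0.01)
  expect_identical(fx1$trial, fx2$trial)
})

test_that("turn injection marks the trial and respects the identity multiplier", {
  fx <- noiseless_trial(n_cycles = 4, drift_slope = 0.5)
  tr <- fx$trial
  same <- inject_turn(tr, at = 12, multiplier = 1)
  expect_equal(same$gy, tr$gy)
  expect_false(is.na(attr(same, "turn_index")))

  whole <- inject_turn(tr, at = 0, multiplier = 2)
  expect_equal(attr(whole, "turn_index"), 1L)
  expect_error(inject_turn(tr, at = 1e5), "outside")
})
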