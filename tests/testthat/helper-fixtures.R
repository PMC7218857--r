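# fixture builders shared across test files

# quiet-standing profile: all joint amplitudes zero
standing_profile <- function(n_cycles = 10L) {
  zero <- list(offset = 0, amp = 0, phase = 0)
  gait_profile(n_cycles = n_cycles,
               harmonics = list(hip = zero, knee = zero, ankle = zero),
               trunk_lean = 0)
}

# noiseless walking trial plus its ground truth; `...` overrides any
# sensor_params() argument (noise defaults to zero here)
noiseless_trial <- function(n_cycles = 8L, fs = 100L, seed = 3L, ...) {
  profile <- gait_profile(n_cycles = n_cycles)
  truth <- generate_joint_trajectories(profile, fs = fs)
  segments <- joints_to_segments(truth, trunk = 90 + profile$trunk_lean)
  args <- utils::modifyList(list(fs = fs, gyro_noise_sd = 0, acc_noise_sd = 0,
                                 seed = seed), list(...))
  sensor <- do.call(sensor_params, args)
  list(trial = synthesize_imu(segments, sensor), truth = truth,
       segments = segments, sensor = sensor)
}

# drift + offset corruption scenario used by the correction tests:
# a two-harmonic ankle-like reference over 30 s at 100 Hz
drift_scenario <- function(drift = 0.05, offset = -4.5, dur = 30, fs = 100) {
  t <- seq(0, dur, by = 1 / fs)
  ref <- 5 + 10 * sin(2 * pi * 0.875 * t) + 5 * sin(4 * pi * 0.875 * t - pi / 2)
  test <- ref + drift * t + offset
  list(t = t, ref = ref, test = test, vel = joint_velocity(test, fs))
}
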