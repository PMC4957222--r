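test_that("zero-variance heart rate gives exactly periodic beats", {
  cfg <- sim_config(duration_s = 10, hr_mean_bpm = 60, hr_sd_bpm = 1e-12,
                    seed = 1)
  set.seed(1)
  cc <- simulate_cardiac_cycle(cfg)
  expect_true(all(abs(diff(cc$beat_times_s) - 1) < 1e-6))
  expect_equal(cc$effective_hr_hz, 1, tolerance = 1e-6)
})

test_that("realized mean heart rate converges to the configured rate", {
  cfg <- sim_config(duration_s = 3600, hr_mean_bpm = 60, hr_sd_bpm = 3,
                    seed = 2)
  set.seed(2)
  cc <- simulate_cardiac_cycle(cfg)
  expect_lt(abs(cc$effective_hr_hz - 1), 0.01)
  expect_true(all(diff(cc$beat_times_s) > 0))
})

test_that("a recording too short for two beats is rejected", {
  cfg <- sim_config(duration_s = 10, seed = 1)
  cfg$duration_s <- 0.5
  expect_error(simulate_cardiac_cycle(cfg), "beats")
})

test_that("cardiac phase is zero at beats and wraps within each cycle", {
  beats <- c(0, 1, 2.2, 3.1)
  expect_equal(cardiac_phase(beats[-4], beats), rep(0, 3))
  expect_equal(cardiac_phase(0.5, beats), pi, tolerance = 1e-12)
  phi <- cardiac_phase(seq(0, 3, by = 0.01), beats)
  expect_true(all(phi >= 0 & phi < 2 * pi))
})

test_that("the ECG trace peaks at the planted R-peak times", {
  ecg <- simulate_ecg(5, fs_eeg = 200, duration_s = 10, noise_mV = 0)
  expect_lt(abs((which.max(ecg) - 1) / 200 - 5), 1 / 200 + 1e-9)
  expect_error(simulate_ecg(numeric(0), 200, 10), "empty")
  expect_error(simulate_ecg(11, 200, 10), "within")
})

test_that("band-passing 10-40 Hz attenuates P/T far more than the QRS", {
  beats <- seq(5, 55, by = 1)
  set.seed(3)
  ecg <- simulate_ecg(beats, 200, 60, noise_mV = 0)
  hi <- filter_ecg(ecg, 200, c(10, 40))
  # energy near the R peaks vs energy in the P/T regions of the cycle
  r_idx <- unlist(lapply(beats, function(b) round(b * 200) + (-5:5)))
  pt_idx <- unlist(lapply(beats, function(b)
    c(round((b - 0.18) * 200) + (-5:5), round((b + 0.28) * 200) + (-5:5))))
  ratio_raw <- sum(ecg[r_idx]^2) / sum(ecg[pt_idx]^2)
  ratio_hi <- sum(hi[r_idx]^2) / sum(hi[pt_idx]^2)
  expect_gt(ratio_hi, 5 * ratio_raw)
})

test_that("the NIRS table has the documented shape and clock", {
  cfg <- sim_config(duration_s = 100, fs_nirs = 50, clock_skew_ppm = 0,
                    seed = 4)
  set.seed(4)
  beats <- simulate_cardiac_cycle(cfg)$beat_times_s
  nir <- simulate_nirs(beats, cfg)
  expect_equal(nrow(nir$table), 5000L)
  expect_identical(names(nir$table), nirs_layout()$name)
  expect_equal(nir$trigger_start_s, 0)
  expect_equal(nir$trigger_end_s, 4999 / 50)
})

test_that("noise-free AC columns are a pure function of cardiac phase", {
  cfg <- sim_config(duration_s = 120, fs_nirs = 40, hr_sd_bpm = 1e-9,
                    nirs_noise_sd = 1e-12, nirs_drift_per_s = 1e-12,
                    clock_skew_ppm = 0, seed = 5)
  set.seed(5)
  beats <- simulate_cardiac_cycle(cfg)$beat_times_s
  nir <- simulate_nirs(beats, cfg)
  phi <- cardiac_phase(nir$sample_times_s, beats)
  ac <- nir$table$brain_AC_2.0_690
  # same phase (up to rounding) must give the same AC value
  key <- round(phi, 6)
  spread <- tapply(ac, key, function(v) diff(range(v)))
  expect_lt(max(spread), 1e-6)
  # nadir of the pulsation at phase 0
  expect_lt(circ_dist(key[which.min(ac)], 0), 0.2)
})

test_that("PD columns carry no cardiac-phase information", {
  cfg <- sim_config(duration_s = 300, seed = 6)
  sim <- simulate_recording(cfg)
  phi <- cardiac_phase(sim$truth$nirs_sample_times_s, sim$truth$beat_times_s)
  r_pd <- circ_lin_cor(phi, sim$recording$nirs$brain_PD_3.0_830)
  r_ac <- circ_lin_cor(phi, sim$recording$nirs$brain_AC_3.0_830)
  expect_lt(r_pd, 0.05)
  expect_gt(r_ac, 0.3)
})

test_that("uncoupled onsets have uniform cardiac phase", {
  for (seed in 1:2) {
    cfg <- sim_config(duration_s = 1800, coupling_kappa = 0, seed = seed)
    sim <- simulate_recording(cfg)
    expect_gt(rayleigh_p(sim$truth$wave_phase_at_onset), 0.01)
  }
})

test_that("strongly coupled onsets concentrate at the preferred phase", {
  cfg <- sim_config(duration_s = 1800, coupling_kappa = 8, seed = 7)
  sim <- simulate_recording(cfg)
  phi_pref <- 2 * pi * 0.15 * (60 / 60)
  expect_lt(circ_dist(circ_mean(sim$truth$wave_phase_at_onset), phi_pref), 0.2)
})

test_that("zero wave rate yields a pure-noise EEG with no onsets", {
  cfg <- sim_config(duration_s = 120, wave_rate_per_min = 0, seed = 8)
  sim <- simulate_recording(cfg)
  expect_length(sim$truth$wave_onsets_s, 0)
  # background only: every channel at the configured noise scale, no deep
  # slow-wave excursions
  expect_equal(unname(apply(sim$recording$eeg, 2, sd)), rep(15, 6),
               tolerance = 0.1)
  expect_gt(min(sim$recording$eeg), -120)
})

test_that("an infeasible wave rate is rejected by the refractory constraint", {
  cfg <- sim_config(duration_s = 120, seed = 9)
  cfg$wave_rate_per_min <- 40
  set.seed(9)
  beats <- simulate_cardiac_cycle(cfg)$beat_times_s
  expect_error(simulate_eeg_with_slow_waves(beats, cfg), "refractory")
})

test_that("planted wave rate tracks the configured rate", {
  cfg <- sim_config(duration_s = 1800, seed = 10)
  sim <- simulate_recording(cfg)
  rate <- length(sim$truth$wave_onsets_s) / 30
  expect_gt(rate, 0.7 * 7.8)
  expect_lt(rate, 1.1 * 7.8)
})

test_that("a fixed seed reproduces the recording exactly", {
  cfg <- sim_config(duration_s = 120, seed = 11)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$recording$eeg, b$recording$eeg)
  expect_identical(a$recording$nirs, b$recording$nirs)
  expect_identical(a$truth$wave_onsets_s, b$truth$wave_onsets_s)
})

test_that("config validation rejects malformed settings", {
  expect_error(sim_config(fs_nirs = 300), "fs_nirs")
  expect_error(sim_config(hr_mean_bpm = -3), "hr_mean_bpm")
  expect_error(sim_config(muscle_ac_frac = 1.5), "muscle_ac_frac")
})
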