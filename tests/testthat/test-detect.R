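test_that("the 1-4 Hz band-pass keeps the band and rejects the rest", {
  fs <- 200
  t <- seq(0, 20, by = 1 / fs)
  in_band <- sin(2 * pi * 2 * t)
  out_band <- sin(2 * pi * 20 * t)
  mid <- 1000:3000                       # avoid edge transients
  g_in <- max(abs(bandpass(in_band, c(1, 4), fs)[mid]))
  g_out <- max(abs(bandpass(out_band, c(1, 4), fs)[mid]))
  expect_gt(g_in, 0.95)
  expect_lt(g_in, 1.05)
  expect_lt(20 * log10(g_out), -20)
  expect_lt(max(abs(bandpass(rep(3, 4000), c(1, 4), fs))), 1e-6)
  expect_error(bandpass(in_band, c(1, 150), fs), "Nyquist")
})

test_that("the negative envelope is the pointwise channel minimum", {
  row <- matrix(c(-1, -3, 2, 0, 5, 1), 1)
  expect_equal(negative_envelope(row), -3)
  m <- matrix(rep(sin(1:50), 6), ncol = 6)
  expect_equal(negative_envelope(m), sin(1:50))
  set.seed(1)
  r <- matrix(rnorm(600), ncol = 6)
  env <- negative_envelope(r)
  expect_true(all(env <= r))                 # brute-force pointwise bound
  expect_equal(env, apply(r, 1, min))
  expect_error(negative_envelope(r[, 1:5]), "6")
})

test_that("candidate half-waves match the analytic sine case", {
  fs <- 200
  t <- seq(-0.25, 1.25, by = 1 / fs)
  env <- -sin(2 * pi * t)
  env[t < 0] <- abs(env[t < 0])            # positive before zero
  cand <- candidate_half_waves(env, fs)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$onset_s, 0.25, tolerance = 1 / fs)   # t starts at -0.25
  expect_equal((cand$up_cross_s - cand$onset_s) * 1000, 500, tolerance = 6)
  expect_equal(cand$neg_peak_uV, -1, tolerance = 1e-3)
  expect_true(cand$onset_s < cand$neg_peak_s &
                cand$neg_peak_s < cand$up_cross_s)
})

test_that("an all-positive envelope yields no candidates", {
  cand <- candidate_half_waves(abs(rnorm(500)) + 0.1, 100)
  expect_equal(nrow(cand), 0L)
})

test_that("candidate count equals a brute-force sign-change scan", {
  set.seed(7)
  for (rep in 1:5) {
    env <- as.numeric(bandpass(rnorm(5000), c(1, 4), 100)) * 10
    cand <- candidate_half_waves(env, 100)
    neg <- env < 0
    # brute force: count interior maximal negative runs
    runs <- rle(neg)
    inner <- sum(runs$values[-c(1, length(runs$values))])
    expect_equal(nrow(cand), inner)
  }
})

test_that("the amplitude threshold arithmetic matches the stated rule", {
  neg <- c(rep(-6, 50), -10, rep(-14, 50))  # median -10, sd exactly 4
  env <- c(neg, rep(2, 20))
  mask <- rep(TRUE, length(env))
  th <- amplitude_threshold(env, mask, fs = 1, amp_sd_mult = 5,
                            amp_scale = "sd")
  expect_equal(as.numeric(th), -30)
  th0 <- amplitude_threshold(env, mask, fs = 1, amp_sd_mult = 0)
  expect_equal(as.numeric(th0), -10)
  expect_error(amplitude_threshold(env[1:30], mask[1:30], fs = 1), "60 s")
  expect_error(amplitude_threshold(abs(env), mask, fs = 1), "negative")
})

test_that("the threshold agrees with an independent recomputation", {
  set.seed(8)
  env <- as.numeric(bandpass(rnorm(20000), c(1, 4), 100)) * 12
  mask <- rep(c(TRUE, FALSE), c(15000, 5000))
  th <- amplitude_threshold(env, mask, fs = 100, amp_sd_mult = 5,
                            amp_scale = "mad")
  neg <- env[1:15000][env[1:15000] < 0]
  expect_equal(as.numeric(th), median(neg) - 5 * mad(neg))
  th_sd <- amplitude_threshold(env, mask, fs = 100, amp_scale = "sd")
  expect_equal(as.numeric(th_sd), median(neg) - 5 * sd(neg))
})

test_that("wavelength, amplitude and slope criteria gate acceptance", {
  cand <- data.frame(
    onset_s = c(1, 2, 3, 4), neg_peak_s = c(1.1, 2.2, 3.2, 4.2),
    neg_peak_uV = c(-90, -90, -10, -90),
    up_cross_s = c(1.2, 2.5, 3.5, 4.5),       # 200, 500, 500, 500 ms
    i_start = c(100, 200, 300, 400), i_end = c(120, 250, 350, 450),
    max_pos_slope_uV_per_s = c(900, 800, 700, 600))
  crit <- detection_criteria(slope_percentile = 0)
  acc <- apply_criteria(cand, -50, crit)
  # 200 ms wave rejected regardless of amplitude; -10 uV fails amplitude
  expect_equal(acc$onset_s, c(2, 4))
  # brute-force filter over the candidate table, slope threshold included
  crit90 <- detection_criteria(slope_percentile = 90)
  acc90 <- apply_criteria(cand, -50, crit90)
  thr <- quantile(cand$max_pos_slope_uV_per_s, 0.9, names = FALSE)
  brute <- cand[cand$neg_peak_uV <= -50 &
                  (cand$up_cross_s - cand$onset_s) * 1000 >= 250 &
                  (cand$up_cross_s - cand$onset_s) * 1000 <= 1250 &
                  cand$max_pos_slope_uV_per_s >= thr, ]
  expect_equal(acc90$onset_s, brute$onset_s)
})

test_that("acceptance equals a brute-force filter on random candidates", {
  set.seed(9)
  n <- 200
  cand <- data.frame(
    onset_s = sort(runif(n, 0, 1000)), neg_peak_s = NA, neg_peak_uV = NA,
    up_cross_s = NA, i_start = NA, i_end = NA, max_pos_slope_uV_per_s = NA)
  cand$up_cross_s <- cand$onset_s + runif(n, 0.1, 1.5)
  cand$neg_peak_s <- (cand$onset_s + cand$up_cross_s) / 2
  cand$neg_peak_uV <- -runif(n, 5, 150)
  cand$max_pos_slope_uV_per_s <- runif(n, 100, 1500)
  crit <- detection_criteria()
  theta <- -60
  acc <- apply_criteria(cand, theta, crit)
  wl <- (cand$up_cross_s - cand$onset_s) * 1000
  thr <- quantile(cand$max_pos_slope_uV_per_s, 0.9, names = FALSE)
  keep <- cand$neg_peak_uV <= theta & wl >= 250 & wl <= 1250 &
    cand$max_pos_slope_uV_per_s >= thr
  expect_equal(acc$onset_s, cand$onset_s[keep])
})

test_that("channel assignment follows the bounded-lag correlation rule", {
  fs <- 200
  t <- seq(0, 4, by = 1 / fs)
  seg_wave <- -80 * sin(pi * pmax(0, pmin(1, (t - 1.5) / 0.5)))
  env <- seg_wave
  i0 <- which(t >= 1.5)[1] + 1L; i1 <- which(t >= 2.0)[1] - 1L
  wave <- data.frame(i_start = i0, i_end = i1)
  crit <- detection_criteria()
  # identical channel: r = 1 at lag 0, included
  eeg6 <- matrix(rep(env, 6), ncol = 6,
                 dimnames = list(NULL, c("F3", "F4", "C3", "C4", "O1", "O2")))
  res <- assign_channels(wave, eeg6, env, theta = -60, crit, fs)
  expect_setequal(res$channels, c("F3", "F4", "C3", "C4", "O1", "O2"))
  expect_true(all(res$r > 0.999))
  expect_true(all(res$lags_ms == 0))
  # channel shifted by 150 ms: best lag within +/-100 ms cannot reach r = 1
  shifted <- c(rep(0, round(0.15 * fs)), env)[seq_along(env)]
  eeg_sh <- eeg6; eeg_sh[, 1] <- shifted
  res_sh <- assign_channels(wave, eeg_sh, env, theta = -60, crit, fs)
  if ("F3" %in% res_sh$channels)
    expect_lt(res_sh$r[res_sh$channels == "F3"], 1 - 1e-6)
  # all-flat channels: wave removed as a false positive
  flat <- eeg6 * 0
  expect_null(assign_channels(wave, flat, env, theta = -60, crit, fs))
})

test_that("detection recovers planted waves with accurate landmarks", {
  sim <- simulate_recording(sim_config(duration_s = 600, seed = 31))
  waves <- detect_slow_waves(sim$recording)
  m <- match_onsets(waves$onset_s, sim$truth$wave_onsets_s)
  expect_gte(m$recall, 0.9)
  expect_gte(m$precision, 0.9)
  expect_lt(abs(median(m$onset_error_s)), 0.05)
  # landmark ordering and wavelength bounds hold for every wave
  expect_true(all(audit_waves(waves)))
  expect_true(all(diff(waves$onset_s) > 0))
})

test_that("a night without planted waves yields almost no detections", {
  sim <- simulate_recording(sim_config(duration_s = 300,
                                       wave_rate_per_min = 0, seed = 32))
  waves <- detect_slow_waves(sim$recording)
  expect_lte(nrow(waves), 2)
})

test_that("detection is invariant to a global amplitude rescaling", {
  sim <- simulate_recording(sim_config(duration_s = 300, seed = 33))
  rec <- sim$recording
  waves1 <- detect_slow_waves(rec)
  rec2 <- rec
  rec2$eeg <- rec$eeg * 2.7
  waves2 <- detect_slow_waves(rec2)
  expect_equal(waves2$onset_s, waves1$onset_s)
  expect_equal(waves2$neg_peak_uV, 2.7 * waves1$neg_peak_uV, tolerance = 1e-9)
  expect_equal(attr(waves2, "theta"), 2.7 * attr(waves1, "theta"),
               tolerance = 1e-9)
})

test_that("manual override lists delete and add waves after detection", {
  waves <- structure(
    data.frame(onset_s = c(10, 20, 30), neg_peak_s = c(10.2, 20.2, 30.2),
               neg_peak_uV = c(-90, -100, -110), up_cross_s = c(10.5, 20.5,
                                                                30.5),
               max_pos_slope_uV_per_s = c(800, 900, 1000),
               n_channels = c(3L, 4L, 5L),
               channels = c("F3", "F3,F4", "C3")),
    class = c("slow_waves", "data.frame"), theta = -60)
  ov <- list(delete_onsets_s = 20.03,
             add = data.frame(onset_s = 25, neg_peak_s = 25.2,
                              neg_peak_uV = -95, up_cross_s = 25.6))
  out <- apply_wave_overrides(waves, ov)
  expect_equal(out$onset_s, c(10, 25, 30))
  expect_equal(attr(out, "theta"), -60)
  p <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(ov, p, auto_unbox = TRUE, digits = NA)
  out2 <- apply_wave_overrides(waves, p)
  expect_equal(out2$onset_s, out$onset_s)
  expect_error(apply_wave_overrides(waves, list(add = data.frame(onset_s = 1))),
               "lack field")
})
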