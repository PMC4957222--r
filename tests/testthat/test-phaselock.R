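test_that("the sine template has unit amplitude and its nadir at the event", {
  tpl <- make_sine_template(1, c(3, 3), fs = 50)
  expect_equal(tpl$values[tpl$times_s == 0], -1)
  minima <- tpl$times_s[abs(tpl$values + 1) < 1e-9]
  expect_equal(minima, -3:3)
  expect_equal(max(tpl$values), 1)
  expect_error(make_sine_template(30, c(3, 3), fs = 50), "Nyquist")
})

test_that("the template self-correlation is 1 at zero lag and at one period", {
  fs <- 50
  tpl <- make_sine_template(1, c(3, 3), fs)
  self <- bounded_xcorr(as.numeric(tpl$values), tpl)
  expect_equal(self$r, 1)
  expect_equal(self$lag_s, 0)          # tie broken toward the smallest |lag|
  res <- bounded_xcorr(as.numeric(tpl$values), tpl$values, max_lag_s = 1.2,
                       fs = fs)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$lag_s, 0)
})

test_that("a delayed trace is recovered at the correct signed lag", {
  fs <- 50
  tpl <- make_sine_template(1, c(3, 3), fs)
  # oscillation whose nadir occurs 0.24 s (12 samples) before the event
  shifted <- -cos(2 * pi * (tpl$times_s + 0.24))
  res <- bounded_xcorr(shifted, tpl)
  expect_gt(res$r, 0.999)
  expect_equal(res$lag_s, 0.24)
})

test_that("bounded_xcorr equals the brute-force shift-and-Pearson oracle", {
  set.seed(61)
  fs <- 25
  for (rep in 1:8) {
    n <- 101
    trace <- rnorm(n)
    template <- rnorm(n)
    L <- 10
    # independent oracle: correlate at every integer shift explicitly
    lags <- -L:L
    r_or <- vapply(lags, function(l) {
      if (l >= 0) cor(trace[1:(n - l)], template[(1 + l):n])
      else cor(trace[(1 - l):n], template[1:(n + l)])
    }, 0)
    best <- which(r_or == max(r_or))
    best <- best[which.min(abs(lags[best]))]
    res <- bounded_xcorr(trace, template, max_lag_s = L / fs, fs = fs)
    expect_equal(res$r, max(r_or), tolerance = 1e-12)
    expect_equal(res$lag_s, lags[best] / fs)
  }
})

test_that("zero-variance overlap is an error", {
  tpl <- make_sine_template(1, c(1, 1), fs = 20)
  expect_error(bounded_xcorr(rep(2, 41), tpl), "zero-variance")
})

test_that("surrogate latencies are uniform draws from the mask", {
  allowed <- seq(100, 200, by = 0.5)
  set.seed(62)
  draws <- surrogate_latencies(10000, allowed)
  expect_true(all(draws %in% allowed))
  cnt <- table(cut(draws, breaks = seq(100, 200, length.out = 11)))
  expect_gt(chisq.test(cnt)$p.value, 1e-4)
  expect_error(surrogate_latencies(5, numeric(0)), "empty")
  # without replacement and a matched count, every mask sample is used once
  small <- c(3, 7, 11, 19)
  expect_setequal(surrogate_latencies(4, small, replace = FALSE), small)
})

test_that("the permutation engine matches the explicit evoked pathway", {
  sim <- simulate_recording(sim_config(duration_s = 240, seed = 63))
  rec <- sim$recording
  waves <- detect_slow_waves(rec)
  sm <- build_sync_map(rec$triggers[["start"]], rec$triggers[["end"]],
                       nrow(rec$nirs), rec$fs_nirs_nominal)
  sig <- brain_ac_signal(rec)
  fs <- rec$fs_nirs_nominal
  tpl <- make_sine_template(1, c(3, 3), fs)
  pl <- permutation_test(sig, fs, waves$onset_s, tpl,
                         allowed_times_s = waves$onset_s, sync = sm,
                         n_perm = 100, seed = 1)
  # explicit route: extract -> per-trial detrend -> average -> bounded xcorr
  ep <- detrend_trials(extract_epochs(sig, fs, waves$onset_s, sync = sm))
  ev <- average_epochs(ep)
  ref <- bounded_xcorr(ev$mean_trace, tpl)
  expect_equal(pl$r, ref$r, tolerance = 1e-10)
  expect_equal(pl$lag_s, ref$lag_s)
})

test_that("p-values are exactly reproducible and follow the proportion rule", {
  sim <- simulate_recording(sim_config(duration_s = 300, coupling_kappa = 8,
                                       seed = 64))
  rec <- sim$recording
  waves <- detect_slow_waves(rec)
  a <- night_phase_lock(rec, waves, n_perm = 150, seed = 9)
  b <- night_phase_lock(rec, waves, n_perm = 150, seed = 9)
  expect_identical(a$null_r, b$null_r)
  expect_identical(a$p_value, b$p_value)
  expect_equal(a$p_value, mean(a$null_r >= a$r))
  expect_length(a$null_r, 150)
  # strong coupling on a quiet night: observed r beyond every surrogate
  expect_equal(a$p_value, 0)
  expect_warning(night_phase_lock(rec, waves, n_perm = 50, seed = 9),
                 "permutations")
})

test_that("landmark locking returns the requested wave landmark times", {
  waves <- data.frame(onset_s = c(1, 5), neg_peak_s = c(1.2, 5.2),
                      up_cross_s = c(1.5, 5.5))
  expect_identical(lock_to_landmark(waves, "onset"), waves$onset_s)
  expect_identical(lock_to_landmark(waves, "neg_peak"), waves$neg_peak_s)
  expect_identical(lock_to_landmark(waves, "up_cross"), waves$up_cross_s)
  expect_error(lock_to_landmark(waves, "zenith"))
  expect_true(all(waves$onset_s < waves$neg_peak_s &
                    waves$neg_peak_s < waves$up_cross_s))
})

test_that("landmark choice shifts the recovered delay by the landmark offset", {
  sim <- simulate_recording(sim_config(duration_s = 600, coupling_kappa = 8,
                                       seed = 65))
  rec <- sim$recording
  waves <- detect_slow_waves(rec)
  pl_on <- night_phase_lock(rec, waves, n_perm = 100, seed = 3,
                            landmark = "onset")
  pl_pk <- night_phase_lock(rec, waves, n_perm = 100, seed = 3,
                            landmark = "neg_peak")
  offset <- median(waves$neg_peak_s - waves$onset_s)
  fs_n <- rec$fs_nirs_nominal
  expect_equal(pl_pk$lag_s, pl_on$lag_s + offset, tolerance = 2 / fs_n)
})
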