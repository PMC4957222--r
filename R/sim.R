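#' Configuration for a synthetic overnight recording
#'
#' Bundles every knob of the multimodal simulator: cardiac rhythm, EEG slow
#' waves and their coupling to cardiac phase, NIRS pulsation and drift, and
#' the clock skew between the EEG and NIRS devices.
#'
#' @param duration_s recording length in seconds.
#' @param fs_eeg EEG/ECG sampling rate, Hz. The polysomnograph clock is the
#'   reference clock for all event times.
#' @param fs_nirs nominal NIRS sampling rate, Hz; must be below `fs_eeg`.
#'   Frequency-domain NIRS systems typically run at 36, 42 or 52 Hz.
#' @param hr_mean_bpm mean heart rate, beats/min.
#' @param hr_sd_bpm beat-to-beat heart-rate variability, beats/min. The SD of
#'   the inter-beat intervals is `60 * hr_sd_bpm / hr_mean_bpm^2` seconds.
#' @param coupling_kappa von Mises concentration of slow-wave onsets around
#'   the preferred cardiac phase; 0 means no coupling.
#' @param coupling_phase_delay_s preferred delay in seconds from the cardiac
#'   pulsation nadir to the slow-wave onset.
#' @param wave_rate_per_min target realized slow-wave rate, waves/min.
#' @param wave_amp_uV magnitude of the slow-wave negative peak, microvolts.
#' @param eeg_noise_uV SD of the band-limited (0.5-30 Hz) EEG background,
#'   microvolts.
#' @param nirs_pulsation_amp peak-to-nadir-ish amplitude of the cardiac
#'   pulsation in the brain-sensor AC columns, light-intensity units (the
#'   waveform is normalized so its nadir is `-nirs_pulsation_amp`).
#' @param nirs_noise_sd white measurement noise SD on every NIRS column,
#'   same units.
#' @param nirs_drift_per_s slow instrumental drift: SD of the drift increment
#'   over one second, units/s (random-walk drift).
#' @param muscle_ac_frac pulsation amplitude at the muscle (control) sensor as
#'   a fraction (<1) of the brain-sensor amplitude.
#' @param clock_skew_ppm deviation of the true NIRS sample clock from nominal,
#'   parts per million.
#' @param ecg_noise_mV additive ECG noise SD, millivolts.
#' @param seed integer seed; a single RNG stream drives every stochastic draw
#'   in [simulate_recording()].
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(duration_s = 1800, fs_eeg = 200, fs_nirs = 42,
                       hr_mean_bpm = 60, hr_sd_bpm = 3,
                       coupling_kappa = 2, coupling_phase_delay_s = 0.15,
                       wave_rate_per_min = 7.8, wave_amp_uV = 175,
                       eeg_noise_uV = 15,
                       nirs_pulsation_amp = 1, nirs_noise_sd = 1,
                       nirs_drift_per_s = 0.02, muscle_ac_frac = 0.3,
                       clock_skew_ppm = 50, ecg_noise_mV = 0.05,
                       seed = 1L) {
  cfg <- list(duration_s = duration_s, fs_eeg = fs_eeg, fs_nirs = fs_nirs,
              hr_mean_bpm = hr_mean_bpm, hr_sd_bpm = hr_sd_bpm,
              coupling_kappa = coupling_kappa,
              coupling_phase_delay_s = coupling_phase_delay_s,
              wave_rate_per_min = wave_rate_per_min,
              wave_amp_uV = wave_amp_uV, eeg_noise_uV = eeg_noise_uV,
              nirs_pulsation_amp = nirs_pulsation_amp,
              nirs_noise_sd = nirs_noise_sd,
              nirs_drift_per_s = nirs_drift_per_s,
              muscle_ac_frac = muscle_ac_frac,
              clock_skew_ppm = clock_skew_ppm,
              ecg_noise_mV = ecg_noise_mV,
              seed = as.integer(seed))
  for (nm in c("duration_s", "fs_eeg", "fs_nirs", "hr_mean_bpm", "hr_sd_bpm",
               "wave_amp_uV", "eeg_noise_uV", "nirs_pulsation_amp",
               "nirs_noise_sd"))
    check_scalar_num(cfg[[nm]], nm)
  for (nm in c("coupling_kappa", "wave_rate_per_min", "nirs_drift_per_s",
               "ecg_noise_mV"))
    check_scalar_num(cfg[[nm]], nm, ge_zero = TRUE)
  check_scalar_num(cfg$clock_skew_ppm, "clock_skew_ppm", positive = FALSE)
  check_scalar_num(cfg$coupling_phase_delay_s, "coupling_phase_delay_s",
                   positive = FALSE)
  if (cfg$fs_nirs >= cfg$fs_eeg) stop_pw("fs_nirs must be below fs_eeg")
  if (cfg$muscle_ac_frac <= 0 || cfg$muscle_ac_frac >= 1)
    stop_pw("muscle_ac_frac must be in (0, 1)")
  tpl <- sw_template_spec()
  if (tpl$neg_s < 0.25 || tpl$neg_s > 1.25)
    stop_pw("slow-wave template negative half-wave must lie in 250-1250 ms")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", sprintf("%.0f s @ %g Hz EEG / %g Hz NIRS", x$duration_s,
                              x$fs_eeg, x$fs_nirs), "\n")
  cat(sprintf("  HR %g +/- %g bpm | waves %g/min, %g uV | kappa %g, delay %g s\n",
              x$hr_mean_bpm, x$hr_sd_bpm, x$wave_rate_per_min, x$wave_amp_uV,
              x$coupling_kappa, x$coupling_phase_delay_s))
  invisible(x)
}

# Fixed slow-wave template geometry (seconds). The brief leading positivity
# makes the planted onset a genuine downward zero-crossing of the negative
# envelope; without it the envelope of six noisy channels sits below zero
# and the detected onset would be set by background noise.
sw_template_spec <- function() {
  list(lead_s = 0.3, neg_s = 0.4, reb_s = 0.5,
       lead_frac = 0.35, reb_frac = 0.4)
}

# Offset (s) between the raw template onset and the downward zero-crossing
# the template exhibits after the canonical 1-4 Hz zero-phase filter. The
# generator pre-shifts insertions by this constant so the planted onset IS
# the landmark the detector measures (the onset is defined on the filtered
# signal in this analysis tradition).
sw_template_filtered_offset <- function(fs, amp_uV = 100) {
  tpl <- sw_template(fs, amp_uV)
  pad <- rep(0, 2L * round(fs))
  bf <- signal::butter(2, c(1, 4) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, c(pad, tpl$samples, pad))
  on_true <- length(pad) + tpl$onset_index
  sgn <- xf > 0
  dc <- which(sgn[-length(sgn)] & !sgn[-1])
  if (!length(dc)) return(0)
  (dc[which.min(abs(dc - on_true))] - on_true) / fs
}

#' Stereotyped slow-wave template
#'
#' Piecewise half-sine wave: a brief leading positivity, the main negative
#' lobe (the down-state), and a smaller positive rebound (the up-state).
#' Time zero of the wave — its onset — is the downward zero-crossing between
#' the leading lobe and the negative lobe.
#'
#' @param fs sampling rate, Hz.
#' @param amp_uV magnitude of the negative peak, microvolts.
#' @return list with `samples` (numeric vector), `onset_index` (1-based index
#'   of the sample at the wave onset) and `spec` (lobe durations).
#' @export
sw_template <- function(fs, amp_uV = 105) {
  sp <- sw_template_spec()
  n_lead <- round(sp$lead_s * fs); n_neg <- round(sp$neg_s * fs)
  n_reb <- round(sp$reb_s * fs)
  lead <- sp$lead_frac * amp_uV * sin(pi * seq_len(n_lead) / (n_lead + 1))
  neg  <- -amp_uV * sin(pi * seq_len(n_neg) / (n_neg + 1))
  reb  <- sp$reb_frac * amp_uV * sin(pi * seq_len(n_reb) / (n_reb + 1))
  list(samples = c(lead, neg, reb), onset_index = n_lead + 1L, spec = sp)
}

#' Simulate the cardiac cycle
#'
#' Draws inter-beat intervals i.i.d. Gaussian (truncated at +/-3 SD) around
#' `60/hr_mean_bpm` and accumulates them into R-peak times. Cardiac phase is
#' defined to increase linearly from 0 to 2*pi within each beat, with phase 0
#' at the R peak, which by convention coincides with the NIRS pulsation nadir.
#'
#' @param config a [sim_config()].
#' @return list with `beat_times_s` (strictly increasing R-peak times) and
#'   `effective_hr_hz` (1 / mean realized inter-beat interval).
#' @export
simulate_cardiac_cycle <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mean_ibi <- 60 / config$hr_mean_bpm
  sd_ibi <- 60 * config$hr_sd_bpm / config$hr_mean_bpm^2
  if (config$duration_s < 2 * mean_ibi)
    stop_pw("duration %.3g s too short for at least 2 beats at %g bpm",
            config$duration_s, config$hr_mean_bpm)
  n_draw <- ceiling(config$duration_s / mean_ibi * 1.3) + 20L
  ibi <- rnorm(n_draw, mean_ibi, sd_ibi)
  bad <- abs(ibi - mean_ibi) > 3 * sd_ibi
  while (any(bad)) {               # truncate at +/- 3 SD by redrawing
    ibi[bad] <- rnorm(sum(bad), mean_ibi, sd_ibi)
    bad <- abs(ibi - mean_ibi) > 3 * sd_ibi
  }
  first <- runif(1, 0, mean_ibi)   # random phase of recording start
  beats <- first + cumsum(c(0, ibi))
  beats <- beats[beats <= config$duration_s]
  if (length(beats) < 2L)
    stop_pw("degenerate recording: fewer than 2 beats in %.3g s",
            config$duration_s)
  list(beat_times_s = beats,
       effective_hr_hz = 1 / mean(diff(beats)))
}

#' Instantaneous cardiac phase at arbitrary times
#'
#' Phase runs linearly from 0 at one R peak to 2*pi at the next. Times before
#' the first or after the last beat are extrapolated with the neighbouring
#' interval and wrapped to `[0, 2*pi)`.
#'
#' @param times_s numeric vector of times (EEG clock, seconds).
#' @param beat_times_s strictly increasing R-peak times.
#' @return phase in radians, same length as `times_s`.
#' @export
cardiac_phase <- function(times_s, beat_times_s) {
  nb <- length(beat_times_s)
  if (nb < 2L) stop_pw("need at least 2 beats to define phase")
  k <- findInterval(times_s, beat_times_s)
  k <- pmin(pmax(k, 1L), nb - 1L)
  frac <- (times_s - beat_times_s[k]) /
    (beat_times_s[k + 1L] - beat_times_s[k])
  (2 * pi * frac) %% (2 * pi)
}

# P-QRS-T morphology: Gaussian bumps at fixed offsets from the R peak
# (seconds, millivolts, seconds SD).
ecg_components <- function() {
  data.frame(name = c("P", "Q", "R", "S", "T"),
             offset = c(-0.180, -0.022, 0, 0.024, 0.280),
             amp = c(0.15, -0.12, 1.0, -0.20, 0.30),
             width = c(0.030, 0.009, 0.011, 0.010, 0.055))
}

#' Simulate an ECG trace from beat times
#'
#' Each beat is a sum of narrow (QRS) and broad (P, T) Gaussian bumps at
#' fixed offsets within the cycle, so band-passing 10-40 Hz isolates the QRS
#' while 0.3-10 Hz retains the slow P/T components.
#'
#' @param beat_times_s R-peak times, seconds.
#' @param fs_eeg sampling rate, Hz.
#' @param duration_s trace length, seconds.
#' @param noise_mV additive white noise SD, millivolts.
#' @return numeric vector, millivolts, `floor(duration_s * fs_eeg)` samples.
#' @export
simulate_ecg <- function(beat_times_s, fs_eeg, duration_s, noise_mV = 0) {
  if (length(beat_times_s) == 0L) stop_pw("empty beat list")
  if (any(beat_times_s < 0 | beat_times_s > duration_s))
    stop_pw("beat times must lie within the trace duration")
  n <- floor(duration_s * fs_eeg)
  ecg <- numeric(n)
  comp <- ecg_components()
  half <- round(0.45 * fs_eeg)     # support window per component
  for (j in seq_len(nrow(comp))) {
    centers <- beat_times_s + comp$offset[j]
    c_idx <- round(centers * fs_eeg) + 1L
    rel <- (-half):half
    for (ci in seq_along(c_idx)) {
      idx <- c_idx[ci] + rel
      ok <- idx >= 1L & idx <= n
      if (!any(ok)) next
      t_rel <- (idx[ok] - 1L) / fs_eeg - centers[ci]
      ecg[idx[ok]] <- ecg[idx[ok]] +
        comp$amp[j] * exp(-0.5 * (t_rel / comp$width[j])^2)
    }
  }
  if (noise_mV > 0) ecg <- ecg + rnorm(n, 0, noise_mV)
  ecg
}

# Asymmetric arterial pulsation waveform: sharp nadir at phase 0, fast drop
# and slower recovery (phase warp), zero mean over the cycle, nadir = -1.
# Kept mildly asymmetric so a sine template correlates high but not at 1.
pulse_waveform <- function(phase, sharpness = 1.2, skew = 0.3) {
  warp <- function(p) p + skew * sin(p)
  raw <- function(p) -exp(sharpness * (cos(warp(p)) - 1))
  grid <- raw(seq(0, 2 * pi, length.out = 2048L))
  m <- mean(grid)
  (raw(phase) - m) / abs(min(grid) - m)
}

#' Column metadata for the 48-column NIRS table
#'
#' Sensor-major ordering: sensor (brain, muscle), then measure (DC, AC, PD),
#' then source-detector distance (2.0, 2.5, 3.0, 3.5 cm), then wavelength
#' (690, 830 nm).
#'
#' @return data.frame with columns `name`, `sensor`, `measure`,
#'   `distance_cm`, `wavelength_nm` (48 rows).
#' @export
nirs_layout <- function() {
  g <- expand.grid(wavelength_nm = c(690, 830),
                   distance_cm = c(2.0, 2.5, 3.0, 3.5),
                   measure = c("DC", "AC", "PD"),
                   sensor = c("brain", "muscle"),
                   stringsAsFactors = FALSE)
  g <- g[, c("sensor", "measure", "distance_cm", "wavelength_nm")]
  g$name <- sprintf("%s_%s_%.1f_%d", g$sensor, g$measure, g$distance_cm,
                    g$wavelength_nm)
  g[, c("name", "sensor", "measure", "distance_cm", "wavelength_nm")]
}

#' Simulate the raw NIRS table
#'
#' Samples are generated on the NIRS device's own clock, which deviates from
#' nominal by `clock_skew_ppm`. AC columns carry slow random-walk drift, the
#' cardiac pulsation (nadir at cardiac phase 0) and white noise; DC and PD
#' columns carry drift and noise only. The muscle sensor's pulsation is
#' attenuated by `muscle_ac_frac`.
#'
#' @param beat_times_s R-peak times on the EEG clock.
#' @param config a [sim_config()].
#' @return list: `table` (data.frame, 48 named columns), `sample_times_s`
#'   (true EEG-clock time of every NIRS sample), `trigger_start_s`,
#'   `trigger_end_s`, `fs_nominal`.
#' @export
simulate_nirs <- function(beat_times_s, config) {
  stopifnot(inherits(config, "sim_config"))
  fs_true <- config$fs_nirs * (1 + config$clock_skew_ppm * 1e-6)
  n <- floor(config$duration_s * fs_true + 1e-9)
  t_k <- (0:(n - 1L)) / fs_true          # trigger_start at EEG time 0
  puls <- pulse_waveform(cardiac_phase(t_k, beat_times_s))
  lay <- nirs_layout()
  base_level <- c(DC = 200, AC = 20, PD = 100)
  cols <- vector("list", nrow(lay))
  # drift is sub-hertz by construction: a per-second Wiener walk (increment
  # SD = nirs_drift_per_s) interpolated onto the sample grid
  t_knots <- seq(0, ceiling(config$duration_s) + 1)
  for (j in seq_len(nrow(lay))) {
    walk <- cumsum(rnorm(length(t_knots), 0, config$nirs_drift_per_s))
    drift <- approx(t_knots, walk, xout = t_k, rule = 2)$y
    x <- base_level[[lay$measure[j]]] + drift +
      rnorm(n, 0, config$nirs_noise_sd)
    if (lay$measure[j] == "AC") {
      amp <- config$nirs_pulsation_amp *
        if (lay$sensor[j] == "muscle") config$muscle_ac_frac else 1
      x <- x + amp * puls
    }
    cols[[j]] <- x
  }
  tab <- as.data.frame(setNames(cols, lay$name))
  list(table = tab, sample_times_s = t_k,
       trigger_start_s = 0, trigger_end_s = t_k[n],
       fs_nominal = config$fs_nirs)
}

#' Simulate six-channel EEG with cardiac-coupled slow waves
#'
#' Candidate onsets form a Poisson stream whose rate is boosted by the mean
#' von Mises acceptance probability, then thinned by
#' `exp(kappa * (cos(phase - preferred) - 1))` so the realized rate matches
#' `wave_rate_per_min` and, with `coupling_kappa = 0`, onset phases are
#' uniform on the circle. The preferred phase corresponds to
#' `coupling_phase_delay_s` after the pulsation nadir at the mean heart rate.
#' Each accepted wave adds the [sw_template()] to all six channels with a
#' small per-channel time jitter (<= 50 ms) and amplitude scatter, on top of
#' band-limited (0.5-30 Hz) background noise.
#'
#' @param beat_times_s R-peak times, seconds.
#' @param config a [sim_config()].
#' @return list: `eeg` (samples x 6 matrix, microvolts, columns
#'   F3/F4/C3/C4/O1/O2), `onsets_s` (planted wave onsets),
#'   `phase_at_onset` (cardiac phase at each onset, radians).
#' @export
simulate_eeg_with_slow_waves <- function(beat_times_s, config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$fs_eeg
  n <- floor(config$duration_s * fs)
  chans <- c("F3", "F4", "C3", "C4", "O1", "O2")
  # Background = diffuse delta activity shared across the scalp (0.5-4 Hz,
  # common to all channels, as in real NREM EEG where sub-threshold delta
  # waves are spatially coherent) + independent broadband sensor/cortical
  # noise (0.5-30 Hz). Total per-channel SD = eeg_noise_uV.
  eeg <- matrix(0, n, 6L, dimnames = list(NULL, chans))
  common <- bandpass(rnorm(n), c(0.5, 4), fs)
  common <- common * (0.8 * config$eeg_noise_uV / sd(common))
  for (ch in 1:6) {
    x <- bandpass(rnorm(n), c(0.5, 30), fs)
    eeg[, ch] <- common + x * (0.6 * config$eeg_noise_uV / sd(x))
  }

  tpl <- sw_template(fs, config$wave_amp_uV)
  tpl_len_s <- length(tpl$samples) / fs
  onsets <- numeric(0); phases <- numeric(0)
  if (config$wave_rate_per_min > 0) {
    lambda <- config$wave_rate_per_min / 60
    refractory <- tpl_len_s
    if (lambda * refractory > 0.5)
      stop_pw("wave_rate_per_min too high for the refractory constraint")
    kap <- config$coupling_kappa
    acc_mean <- exp(-kap) * besselI(kap, 0)   # E[acceptance] under uniform phase
    lambda_cand <- lambda / acc_mean
    lo <- 4; hi <- config$duration_s - tpl_len_s - 4
    if (hi > lo) {
      n_cand <- ceiling((hi - lo) * lambda_cand + 10 * sqrt(lambda_cand * (hi - lo)))
      cand <- lo + cumsum(rexp(n_cand, lambda_cand))
      cand <- cand[cand <= hi]
      phi <- cardiac_phase(cand, beat_times_s)
      phi_pref <- (2 * pi * config$coupling_phase_delay_s *
                     config$hr_mean_bpm / 60) %% (2 * pi)
      keep <- runif(length(cand)) < exp(kap * (cos(phi - phi_pref) - 1))
      cand <- cand[keep]; phi <- phi[keep]
      if (length(cand)) {                    # refractory thinning scan
        ok <- logical(length(cand)); last <- -Inf
        for (i in seq_along(cand)) {
          if (cand[i] - last >= refractory) { ok[i] <- TRUE; last <- cand[i] }
        }
        onsets <- cand[ok]; phases <- phi[ok]
      }
    }
  }
  filt_off <- sw_template_filtered_offset(fs)
  for (w in seq_along(onsets)) {
    for (ch in 1:6) {
      jit <- max(-0.05, min(0.05, rnorm(1, 0, 0.01)))
      gain <- runif(1, 0.9, 1.1)
      i0 <- round((onsets[w] - filt_off + jit) * fs) + 1L -
        (tpl$onset_index - 1L)
      idx <- i0 + seq_along(tpl$samples) - 1L
      ok <- idx >= 1L & idx <= n
      eeg[idx[ok], ch] <- eeg[idx[ok], ch] + gain * tpl$samples[ok]
    }
  }
  list(eeg = eeg, onsets_s = onsets, phase_at_onset = phases)
}

#' Simulate a complete synchronized night
#'
#' Composes the cardiac cycle, ECG, six-channel EEG with planted slow waves,
#' the 48-column NIRS table on its own (skewed) clock, an all-N3 hypnogram
#' and the NIRS start/end triggers. All randomness flows from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `recording` (class `sw_recording`: `eeg`, `ecg`,
#'   `fs_eeg`, `nirs`, `fs_nirs_nominal`, `hypnogram`, `artifacts`,
#'   `triggers`) and `truth` (class `sim_truth`: `beat_times_s`,
#'   `wave_onsets_s`, `wave_phase_at_onset`, `effective_hr_hz`,
#'   `trigger_times_s`, `nirs_sample_times_s`, `config`).
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cc <- simulate_cardiac_cycle(config)
  ecg <- simulate_ecg(cc$beat_times_s, config$fs_eeg, config$duration_s,
                      config$ecg_noise_mV)
  sw <- simulate_eeg_with_slow_waves(cc$beat_times_s, config)
  nir <- simulate_nirs(cc$beat_times_s, config)
  n_epoch <- ceiling(config$duration_s / 30)
  hyp <- data.frame(epoch_index = 0:(n_epoch - 1L), stage = "N3")
  art <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    kind = character(0))
  rec <- structure(list(eeg = sw$eeg, ecg = ecg, fs_eeg = config$fs_eeg,
                        nirs = nir$table, fs_nirs_nominal = config$fs_nirs,
                        hypnogram = hyp, artifacts = art,
                        triggers = c(start = nir$trigger_start_s,
                                     end = nir$trigger_end_s)),
                   class = "sw_recording")
  truth <- structure(list(beat_times_s = cc$beat_times_s,
                          wave_onsets_s = sw$onsets_s,
                          wave_phase_at_onset = sw$phase_at_onset,
                          effective_hr_hz = cc$effective_hr_hz,
                          trigger_times_s = c(nir$trigger_start_s,
                                              nir$trigger_end_s),
                          nirs_sample_times_s = nir$sample_times_s,
                          config = config),
                     class = "sim_truth")
  list(recording = rec, truth = truth)
}

#' @export
print.sw_recording <- function(x, ...) {
  cat(sprintf("<sw_recording> %.0f s: EEG 6 x %d @ %g Hz, NIRS %d x %d @ %g Hz\n",
              nrow(x$eeg) / x$fs_eeg, nrow(x$eeg), x$fs_eeg,
              nrow(x$nirs), ncol(x$nirs), x$fs_nirs_nominal))
  invisible(x)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d beats (%.3f Hz), %d planted waves\n",
              length(x$beat_times_s), x$effective_hr_hz,
              length(x$wave_onsets_s)))
  invisible(x)
}
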