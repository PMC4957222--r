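#' Slow-wave detection criteria
#'
#' Canonical-wave criteria applied to the 1-4 Hz negative envelope of the six
#' EEG channels: an amplitude threshold of `amp_sd_mult` standard deviations
#' below the median negative activity, a negative half-wave duration
#' (`wavelength_ms`), and a maximum positive slope in the
#' `slope_percentile`-th percentile. Channel membership requires a bounded-lag
#' correlation of at least `channel_r_min` within `channel_max_lag_ms` and a
#' negative channel minimum of at least `channel_amp_frac` of the amplitude
#' threshold.
#'
#' @param band_hz band-pass edges for the canonical wave, Hz.
#' @param amp_sd_mult SD multiplier for the amplitude threshold.
#' @param wavelength_ms allowed negative half-wave duration range, ms.
#' @param slope_percentile percentile (0-100) the wave's maximal positive
#'   slope must reach.
#' @param slope_population population over which the slope percentile is
#'   taken: `"all"` candidates (default) or only those `"passing"` the
#'   amplitude and wavelength criteria.
#' @param channel_r_min minimum envelope-to-channel correlation.
#' @param channel_max_lag_ms lag bound for the channel correlation, ms.
#' @param channel_amp_frac fraction of the amplitude threshold a channel's
#'   negative peak must reach.
#' @param amp_stat statistics used for the threshold: over negative-valued
#'   envelope `"samples"` (default) or over candidate `"peaks"`.
#' @param amp_scale scale estimator for the threshold: `"mad"` (default,
#'   Gaussian-consistent median absolute deviation) or plain `"sd"`. The
#'   robust choice keeps the threshold anchored to the background activity:
#'   the slow waves themselves are rare but deep, and with a plain SD their
#'   own contribution drags the threshold down in proportion to their
#'   amplitude.
#' @return object of class `detection_criteria`.
#' @export
detection_criteria <- function(band_hz = c(1, 4), amp_sd_mult = 5,
                               wavelength_ms = c(250, 1250),
                               slope_percentile = 90,
                               slope_population = c("all", "passing"),
                               channel_r_min = 0.9, channel_max_lag_ms = 100,
                               channel_amp_frac = 0.10,
                               amp_stat = c("samples", "peaks"),
                               amp_scale = c("mad", "sd")) {
  if (slope_percentile < 0 || slope_percentile >= 100)
    stop_pw("slope_percentile must be in [0, 100)")
  if (channel_r_min <= 0 || channel_r_min > 1)
    stop_pw("channel_r_min must be in (0, 1]")
  if (channel_amp_frac <= 0 || channel_amp_frac > 1)
    stop_pw("channel_amp_frac must be in (0, 1]")
  if (any(wavelength_ms <= 0) || wavelength_ms[2] <= wavelength_ms[1])
    stop_pw("wavelength_ms must be an ordered positive pair")
  structure(list(band_hz = band_hz, amp_sd_mult = amp_sd_mult,
                 wavelength_ms = wavelength_ms,
                 slope_percentile = slope_percentile,
                 slope_population = match.arg(slope_population),
                 channel_r_min = channel_r_min,
                 channel_max_lag_ms = channel_max_lag_ms,
                 channel_amp_frac = channel_amp_frac,
                 amp_stat = match.arg(amp_stat),
                 amp_scale = match.arg(amp_scale)),
            class = "detection_criteria")
}

#' Negative envelope of the six EEG channels
#'
#' Pointwise minimum across channels; the canonical trace on which all
#' slow-wave criteria operate.
#'
#' @param eeg samples x channels matrix (6 channels unless
#'   `allow_other_count`).
#' @param allow_other_count permit a channel count other than 6.
#' @return numeric vector.
#' @export
negative_envelope <- function(eeg, allow_other_count = FALSE) {
  if (!is.matrix(eeg)) stop_pw("`eeg` must be a matrix")
  if (ncol(eeg) != 6L && !allow_other_count)
    stop_pw("expected 6 EEG channels, got %d", ncol(eeg))
  Reduce(pmin, lapply(seq_len(ncol(eeg)), function(j) eeg[, j]))
}

#' Candidate half-waves of the envelope
#'
#' Every maximal negative excursion (downward zero-crossing to the subsequent
#' upward zero-crossing) lying fully inside the mask yields one candidate.
#' Crossing times are linearly interpolated between samples; excursions
#' truncated by the recording edges are discarded.
#'
#' @param envelope canonical trace, microvolts.
#' @param fs sampling rate, Hz.
#' @param mask optional logical vector (TRUE = usable sample).
#' @return data.frame: `onset_s`, `neg_peak_s`, `neg_peak_uV`, `up_cross_s`,
#'   `i_start`, `i_end` (sample span of the excursion),
#'   `max_pos_slope_uV_per_s`.
#' @export
candidate_half_waves <- function(envelope, fs, mask = NULL) {
  n <- length(envelope)
  if (is.null(mask)) mask <- rep(TRUE, n)
  neg <- envelope < 0
  r <- rle(neg)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  keep <- r$values & starts > 1L & ends < n          # interior excursions only
  starts <- starts[keep]; ends <- ends[keep]
  out <- vector("list", length(starts))
  t_of <- function(i) (i - 1) / fs
  for (k in seq_along(starts)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (!all(mask[i0:i1])) next
    y0 <- envelope[i0 - 1L]; y1 <- envelope[i0]
    onset <- t_of(i0 - 1L) + if (y0 == y1) 0 else (y0 / (y0 - y1)) / fs
    ya <- envelope[i1]; yb <- envelope[i1 + 1L]
    upx <- t_of(i1) + if (ya == yb) 0 else (ya / (ya - yb)) / fs
    imin <- i0 - 1L + which.min(envelope[i0:i1])
    seg <- envelope[imin:(i1 + 1L)]
    slope <- if (length(seg) > 1L) max(diff(seg)) * fs else NA_real_
    out[[k]] <- c(onset, t_of(imin), envelope[imin], upx, i0, i1, slope)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out))
    return(data.frame(onset_s = numeric(0), neg_peak_s = numeric(0),
                      neg_peak_uV = numeric(0), up_cross_s = numeric(0),
                      i_start = integer(0), i_end = integer(0),
                      max_pos_slope_uV_per_s = numeric(0)))
  data.frame(onset_s = out[, 1], neg_peak_s = out[, 2], neg_peak_uV = out[, 3],
             up_cross_s = out[, 4], i_start = as.integer(out[, 5]),
             i_end = as.integer(out[, 6]), max_pos_slope_uV_per_s = out[, 7])
}

#' Amplitude threshold from the median negative activity
#'
#' `theta = median(neg) - amp_sd_mult * scale(neg)` where `neg` are either
#' the negative-valued masked envelope samples (default) or the candidate
#' negative-peak amplitudes (`amp_stat = "peaks"`, pass `candidates`), and
#' `scale` is the Gaussian-consistent MAD (default) or the plain SD.
#'
#' @param envelope canonical trace.
#' @param mask logical vector; must select at least 60 s of signal.
#' @param fs sampling rate, Hz.
#' @param amp_sd_mult SD multiplier (default 5).
#' @param amp_stat,amp_scale see [detection_criteria()].
#' @param candidates candidate table (required for `amp_stat = "peaks"`).
#' @return threshold in microvolts (negative), with attributes `median` and
#'   `scale` for logging.
#' @export
amplitude_threshold <- function(envelope, mask, fs, amp_sd_mult = 5,
                                amp_stat = "samples", amp_scale = "mad",
                                candidates = NULL) {
  if (sum(mask) < 60 * fs)
    stop_pw("mask selects less than 60 s of signal")
  neg <- if (amp_stat == "peaks") {
    if (is.null(candidates)) stop_pw("amp_stat='peaks' needs `candidates`")
    candidates$neg_peak_uV
  } else {
    e <- envelope[mask]
    e[e < 0]
  }
  if (!length(neg)) stop_pw("no negative samples available for the threshold")
  sc <- if (amp_scale == "mad") stats::mad(neg) else sd(neg)
  theta <- median(neg) - amp_sd_mult * sc
  structure(theta, median = median(neg), scale = sc)
}

#' Apply amplitude, wavelength and slope criteria to candidates
#'
#' A candidate is accepted iff its negative peak reaches `theta`, its
#' negative half-wave duration lies in `wavelength_ms`, and its maximal
#' positive slope (between negative peak and upward zero-crossing) reaches
#' the `slope_percentile`-th percentile of candidate slopes. The percentile
#' population is controlled by `slope_population` (see
#' [detection_criteria()]). Candidates are disjoint excursions, so accepted
#' waves cannot overlap.
#'
#' @param candidates output of [candidate_half_waves()].
#' @param theta amplitude threshold (negative, microvolts).
#' @param criteria a [detection_criteria()].
#' @return accepted subset of `candidates`, with attribute `slope_threshold`.
#' @export
apply_criteria <- function(candidates, theta, criteria) {
  if (!nrow(candidates)) return(candidates)
  wl <- (candidates$up_cross_s - candidates$onset_s) * 1000
  pass_amp <- candidates$neg_peak_uV <= theta
  pass_wl <- wl >= criteria$wavelength_ms[1] & wl <= criteria$wavelength_ms[2]
  pool <- if (criteria$slope_population == "passing") {
    candidates$max_pos_slope_uV_per_s[pass_amp & pass_wl]
  } else {
    candidates$max_pos_slope_uV_per_s
  }
  slope_thr <- if (length(pool) && criteria$slope_percentile > 0) {
    quantile(pool, criteria$slope_percentile / 100, na.rm = TRUE, names = FALSE)
  } else {
    -Inf
  }
  pass_slope <- !is.na(candidates$max_pos_slope_uV_per_s) &
    candidates$max_pos_slope_uV_per_s >= slope_thr
  acc <- candidates[pass_amp & pass_wl & pass_slope, , drop = FALSE]
  attr(acc, "slope_threshold") <- slope_thr
  acc
}

#' Assign channels to an accepted canonical wave
#'
#' Cross-correlates the envelope segment (onset to upward zero-crossing) with
#' each channel over lags up to `channel_max_lag_ms`. A channel participates
#' iff max r >= `channel_r_min`, its minimum in the wave window is negative,
#' and that minimum reaches `channel_amp_frac * |theta|`. A wave with no
#' participating channel is a false positive.
#'
#' @param wave one row of the accepted candidate table.
#' @param filtered_eeg samples x 6 band-passed EEG matrix, or a named list
#'   of its columns (faster when called repeatedly).
#' @param envelope canonical trace.
#' @param theta amplitude threshold.
#' @param criteria a [detection_criteria()].
#' @param fs sampling rate, Hz.
#' @return list `channels` (character, possibly empty), `lags_ms`, `r` —
#'   or NULL when no channel qualifies.
#' @export
assign_channels <- function(wave, filtered_eeg, envelope, theta, criteria, fs) {
  if (is.matrix(filtered_eeg))
    filtered_eeg <- setNames(lapply(seq_len(ncol(filtered_eeg)),
                                    function(j) filtered_eeg[, j]),
                             colnames(filtered_eeg))
  L <- round(criteria$channel_max_lag_ms / 1000 * fs)
  i0 <- wave$i_start; i1 <- wave$i_end
  n <- length(filtered_eeg[[1]])
  if (i0 - L < 1L || i1 + L > n) return(NULL)       # too close to the edge
  seg <- envelope[i0:i1]
  segc <- seg - mean(seg)
  seg_norm <- sqrt(sum(segc^2))
  if (seg_norm == 0) return(NULL)
  lag_seq <- (-L):L
  lag_ord <- order(abs(lag_seq), lag_seq)        # ties -> smallest |lag|
  idx <- outer(lag_seq, i0:i1, "+")
  channels <- character(0); lags <- numeric(0); rs <- numeric(0)
  for (ch in names(filtered_eeg)) {
    chan <- filtered_eeg[[ch]]
    Y <- matrix(chan[idx], nrow = length(lag_seq))
    Yc <- Y - rowMeans(Y)
    denom <- sqrt(rowSums(Yc^2)) * seg_norm
    r_all <- as.numeric(Yc %*% segc) / denom
    r_all[denom == 0] <- -Inf
    best <- lag_ord[which.max(r_all[lag_ord])]
    best_r <- r_all[best]; best_l <- lag_seq[best]
    ch_min <- min(chan[i0:i1])
    if (best_r >= criteria$channel_r_min && ch_min < 0 &&
        abs(ch_min) >= criteria$channel_amp_frac * abs(theta)) {
      channels <- c(channels, ch)
      lags <- c(lags, best_l / fs * 1000)
      rs <- c(rs, best_r)
    }
  }
  if (!length(channels)) return(NULL)
  list(channels = channels, lags_ms = lags, r = rs)
}

#' Detect slow waves in a recording
#'
#' Full detection chain: band-pass the six EEG channels, take the negative
#' envelope, list candidate half-waves inside the N2/N3 artifact-free mask,
#' apply the amplitude / wavelength / slope criteria, then keep only waves
#' with at least one participating channel.
#'
#' @param recording an `sw_recording` (or any list with `eeg`, `fs_eeg`,
#'   `hypnogram`, `artifacts`).
#' @param criteria a [detection_criteria()].
#' @param stages sleep stages searched (default N2 + N3).
#' @return data.frame of class `slow_waves`: `onset_s`, `neg_peak_s`,
#'   `neg_peak_uV`, `up_cross_s`, `max_pos_slope_uV_per_s`, `n_channels`,
#'   `channels` (comma-separated labels). Attributes: `theta`,
#'   `slope_threshold`, `waves_per_min`, `fs`.
#' @export
detect_slow_waves <- function(recording, criteria = detection_criteria(),
                              stages = c("N2", "N3")) {
  fs <- recording$fs_eeg
  filt <- bandpass(recording$eeg, criteria$band_hz, fs)
  colnames(filt) <- colnames(recording$eeg)
  env <- negative_envelope(filt)
  mask <- stage_mask(recording$hypnogram, nrow(filt), fs, stages,
                     recording$artifacts)
  cand <- candidate_half_waves(env, fs, mask)
  theta <- amplitude_threshold(env, mask, fs, criteria$amp_sd_mult,
                               criteria$amp_stat, criteria$amp_scale, cand)
  acc <- apply_criteria(cand, theta, criteria)
  filt_cols <- setNames(lapply(seq_len(ncol(filt)), function(j) filt[, j]),
                        colnames(filt))
  rows <- list()
  for (k in seq_len(nrow(acc))) {
    ass <- assign_channels(acc[k, ], filt_cols, env, theta, criteria, fs)
    if (is.null(ass)) next
    rows[[length(rows) + 1L]] <-
      data.frame(onset_s = acc$onset_s[k], neg_peak_s = acc$neg_peak_s[k],
                 neg_peak_uV = acc$neg_peak_uV[k],
                 up_cross_s = acc$up_cross_s[k],
                 max_pos_slope_uV_per_s = acc$max_pos_slope_uV_per_s[k],
                 n_channels = length(ass$channels),
                 channels = paste(ass$channels, collapse = ","))
  }
  waves <- if (length(rows)) do.call(rbind, rows) else
    data.frame(onset_s = numeric(0), neg_peak_s = numeric(0),
               neg_peak_uV = numeric(0), up_cross_s = numeric(0),
               max_pos_slope_uV_per_s = numeric(0), n_channels = integer(0),
               channels = character(0))
  waves <- waves[order(waves$onset_s), , drop = FALSE]
  rownames(waves) <- NULL
  attr(waves, "theta") <- as.numeric(theta)
  attr(waves, "theta_median") <- attr(theta, "median")
  attr(waves, "theta_scale") <- attr(theta, "scale")
  attr(waves, "slope_threshold") <- attr(acc, "slope_threshold")
  attr(waves, "waves_per_min") <- nrow(waves) / (sum(mask) / fs / 60)
  attr(waves, "fs") <- fs
  class(waves) <- c("slow_waves", "data.frame")
  waves
}

#' Re-check every detected wave against the criteria (post-hoc audit)
#'
#' Independent confirmation that each accepted wave satisfies the landmark
#' ordering, amplitude, and wavelength criteria it was selected under.
#'
#' @param waves a `slow_waves` table.
#' @param criteria the criteria used at detection time.
#' @return logical vector, one entry per wave.
#' @export
audit_waves <- function(waves, criteria = detection_criteria()) {
  if (!nrow(waves)) return(logical(0))
  theta <- attr(waves, "theta")
  wl <- (waves$up_cross_s - waves$onset_s) * 1000
  waves$onset_s < waves$neg_peak_s & waves$neg_peak_s < waves$up_cross_s &
    waves$neg_peak_uV < 0 & waves$neg_peak_uV <= theta &
    wl >= criteria$wavelength_ms[1] & wl <= criteria$wavelength_ms[2] &
    waves$n_channels >= 1L
}

#' Match detected onsets to ground-truth onsets
#'
#' Greedy one-to-one matching within `tol_s`; used to score detection
#' recall/precision against planted waves.
#'
#' @param detected_s,truth_s numeric vectors of onset times.
#' @param tol_s matching tolerance, seconds (default 0.25).
#' @return list `n_match`, `recall`, `precision`, `f1`,
#'   `onset_error_s` (matched detected minus truth).
#' @export
match_onsets <- function(detected_s, truth_s, tol_s = 0.25) {
  used <- logical(length(detected_s))
  err <- numeric(0); n_match <- 0L
  for (t0 in truth_s) {
    d <- abs(detected_s - t0)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_s) {
      used[j] <- TRUE; n_match <- n_match + 1L
      err <- c(err, detected_s[j] - t0)
    }
  }
  list(n_match = n_match,
       recall = if (length(truth_s)) n_match / length(truth_s) else NA_real_,
       precision = if (length(detected_s)) n_match / length(detected_s)
                   else NA_real_,
       f1 = if (n_match) 2 * n_match / (length(truth_s) + length(detected_s))
            else 0,
       onset_error_s = err)
}

#' Apply a manual wave override list
#'
#' Semi-automatic review is supported only through an external override
#' list applied after detection: waves can be deleted by onset time and
#' fully specified waves added. No interactive editing exists.
#'
#' @param waves a `slow_waves` table.
#' @param overrides a list (or path to a JSON file) with optional elements
#'   `delete_onsets_s` (numeric; waves within `tol_s` of these onsets are
#'   removed) and `add` (data.frame/list of rows with the `slow_waves`
#'   columns).
#' @param tol_s matching tolerance for deletions, seconds.
#' @return the edited table, re-sorted by onset.
#' @export
apply_wave_overrides <- function(waves, overrides, tol_s = 0.1) {
  if (is.character(overrides))
    overrides <- jsonlite::read_json(overrides, simplifyVector = TRUE)
  att <- attributes(waves)
  if (!is.null(overrides$delete_onsets_s) && nrow(waves)) {
    drop <- vapply(waves$onset_s, function(o)
      any(abs(overrides$delete_onsets_s - o) <= tol_s), TRUE)
    waves <- waves[!drop, , drop = FALSE]
  }
  if (!is.null(overrides$add)) {
    add <- as.data.frame(overrides$add)
    miss <- setdiff(c("onset_s", "neg_peak_s", "neg_peak_uV", "up_cross_s"),
                    names(add))
    if (length(miss))
      stop_pw("added waves lack field(s): %s", paste(miss, collapse = ", "))
    for (nm in setdiff(names(waves), names(add))) add[[nm]] <- NA
    waves <- rbind(waves, add[, names(waves)])
  }
  waves <- waves[order(waves$onset_s), , drop = FALSE]
  rownames(waves) <- NULL
  for (a in setdiff(names(att), c("row.names", "names")))
    attr(waves, a) <- att[[a]]
  waves
}
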