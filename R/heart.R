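#' Detect R peaks in an ECG trace
#'
#' Energy-based detector: band-pass 10-40 Hz to isolate the QRS complex,
#' square, smooth (80 ms moving average), threshold at a fraction of a high
#' quantile of the smoothed energy, then refine each detection to the local
#' extremum of the raw trace. Squaring makes the detector invariant to both
#' amplitude scaling and polarity.
#'
#' @param ecg numeric vector, millivolts.
#' @param fs sampling rate, Hz.
#' @param refractory_s minimum beat spacing, seconds (default 0.25).
#' @return strictly increasing beat times, seconds.
#' @export
detect_r_peaks <- function(ecg, fs, refractory_s = 0.25) {
  if (length(ecg) < 10 * fs) stop_pw("ECG trace must be at least 10 s long")
  if (diff(range(ecg)) == 0) stop_pw("no QRS energy found (flat ECG?)")
  f <- bandpass(ecg, c(10, 40), fs)
  e <- f^2
  w <- max(1L, round(0.08 * fs))
  es <- as.numeric(stats::filter(e, rep(1 / w, w), sides = 2))
  es[is.na(es)] <- 0
  thr <- 0.25 * quantile(es, 0.999, names = FALSE)
  if (!is.finite(thr) || thr <= 0) stop_pw("no QRS energy found (flat ECG?)")
  above <- es > thr
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- c(1L, head(ends, -1) + 1L)
  regions <- cbind(starts[r$values], ends[r$values])
  if (!nrow(regions)) stop_pw("no R peaks found")
  half <- round(0.05 * fs)
  centered <- ecg - median(ecg)
  peaks <- apply(regions, 1L, function(rg) {
    i <- rg[1] - 1L + which.max(es[rg[1]:rg[2]])
    a <- max(1L, i - half); b <- min(length(ecg), i + half)
    a - 1L + which.max(abs(centered[a:b]))
  })
  peaks <- sort(unique(peaks))
  # refractory: keep the stronger of any two peaks closer than refractory_s
  keep <- rep(TRUE, length(peaks))
  last <- 1L
  for (i in seq_along(peaks)[-1]) {
    if ((peaks[i] - peaks[last]) / fs < refractory_s) {
      if (es[peaks[i]] > es[peaks[last]]) { keep[last] <- FALSE; last <- i }
      else keep[i] <- FALSE
    } else last <- i
  }
  (peaks[keep] - 1) / fs
}

#' Mean heart rate within a sleep stage
#'
#' `mean_hz` is the reciprocal of the mean inter-beat interval over intervals
#' whose both endpoints fall in epochs of the requested stage.
#'
#' @param beat_times_s R-peak times, seconds (EEG clock).
#' @param hypnogram data.frame `epoch_index`, `stage`.
#' @param stage stage label(s) to use (default `"N3"`).
#' @return list of class `heart_rate_estimate`: `mean_hz`, `mean_bpm`,
#'   `n_beats`, `stage_used`.
#' @export
mean_heart_rate <- function(beat_times_s, hypnogram, stage = "N3") {
  ep <- floor(beat_times_s / 30)
  stage_of <- setNames(hypnogram$stage, hypnogram$epoch_index)
  in_stage <- stage_of[as.character(ep)] %in% stage
  in_stage[is.na(in_stage)] <- FALSE
  ok <- in_stage[-length(in_stage)] & in_stage[-1]
  ibis <- diff(beat_times_s)[ok]
  if (sum(in_stage) < 2L || !length(ibis))
    stop_pw("fewer than 2 beats inside stage %s; consider falling back to N2+N3",
            paste(stage, collapse = "+"))
  mean_hz <- 1 / mean(ibis)
  structure(list(mean_hz = mean_hz, mean_bpm = 60 * mean_hz,
                 n_beats = sum(in_stage),
                 stage_used = paste(stage, collapse = "+")),
            class = "heart_rate_estimate")
}

#' @export
print.heart_rate_estimate <- function(x, ...) {
  cat(sprintf("<heart_rate_estimate> %.2f bpm (%.4f Hz) from %d beats in %s\n",
              x$mean_bpm, x$mean_hz, x$n_beats, x$stage_used))
  invisible(x)
}

#' Band-limited ECG variants
#'
#' Zero-phase band-pass used to dissociate the slow P/T components
#' (0.3-10 Hz) from the fast QRS complex (10-40 Hz) before building the
#' evoked response.
#'
#' @param ecg numeric vector.
#' @param fs sampling rate, Hz.
#' @param band length-2 numeric band edges in Hz.
#' @return filtered trace.
#' @export
filter_ecg <- function(ecg, fs, band) bandpass(ecg, band, fs)
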