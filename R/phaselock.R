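#' Heart-rate sine template
#'
#' `s(t) = -cos(2*pi*freq_hz*t)` sampled on the evoked-response grid, so the
#' template's local minimum (the pulsation nadir) sits exactly at the event
#' (t = 0) and the amplitude is 1.
#'
#' @param freq_hz template frequency, Hz — the participant's mean N3 heart
#'   rate.
#' @param window_s length-2 window in seconds before/after the event.
#' @param fs sampling rate of the evoked trace, Hz.
#' @return object of class `sine_template`: `values`, `times_s`, `freq_hz`,
#'   `fs`.
#' @export
make_sine_template <- function(freq_hz, window_s = c(3, 3), fs) {
  check_scalar_num(freq_hz, "freq_hz")
  if (freq_hz >= fs / 2)
    stop_pw("template frequency %.3g Hz at or above Nyquist (%.3g Hz)",
            freq_hz, fs / 2)
  times <- ((-round(window_s[1] * fs)):(round(window_s[2] * fs))) / fs
  structure(list(values = -cos(2 * pi * freq_hz * times), times_s = times,
                 freq_hz = freq_hz, fs = fs),
            class = "sine_template")
}

# Row-wise bounded-lag Pearson correlation of trace rows against a template.
# Positive lag l: template advanced by l samples, i.e. the template feature
# (nadir) occurs l samples BEFORE the event in the trace. Lags are visited in
# order of increasing |lag| so ties resolve toward the smallest |lag|.
# Returns list(r, lag) vectors, one entry per row of `traces`.
xcorr_rows <- function(traces, template, L) {
  if (!is.matrix(traces)) traces <- matrix(traces, nrow = 1L)
  m <- ncol(traces)
  if (L >= m) stop_pw("max lag must be smaller than the window")
  lags <- (-L):L
  lags <- lags[order(abs(lags), lags)]
  best_r <- rep(-Inf, nrow(traces)); best_l <- integer(nrow(traces))
  any_ok <- rep(FALSE, nrow(traces))
  for (l in lags) {
    if (l >= 0) { ti <- seq_len(m - l); bi <- (1 + l):m }
    else { ti <- (1 - l):m; bi <- seq_len(m + l) }
    b <- template[bi]
    bc <- b - mean(b)
    nb <- sqrt(sum(bc^2))
    if (nb == 0) next
    A <- traces[, ti, drop = FALSE]
    Ac <- A - rowMeans(A)
    na <- sqrt(rowSums(Ac^2))
    r <- as.numeric(Ac %*% bc) / (na * nb)
    ok <- is.finite(r) & na > 0
    any_ok <- any_ok | ok
    upd <- ok & r > best_r
    best_r[upd] <- r[upd]; best_l[upd] <- l
  }
  if (!all(any_ok))
    stop_pw("zero-variance overlap: correlation undefined at every lag")
  list(r = best_r, lag = best_l)
}

#' Bounded-lag cross-correlation against the sine template
#'
#' Pearson correlation on the overlapping region for every integer-sample lag
#' within `max_lag_s`, returning the maximum and the lag achieving it (ties
#' broken toward the smallest |lag|). Positive `lag_s` means the template's
#' nadir precedes the event by `lag_s` — the phase delay from pulsation nadir
#' to slow-wave onset reported by this pipeline.
#'
#' @param trace evoked trace (numeric vector).
#' @param template a [make_sine_template()] or numeric vector on the same
#'   grid.
#' @param max_lag_s lag bound, seconds; default half the template period.
#' @param fs sampling rate (taken from the template if omitted).
#' @return list: `r`, `lag_s`.
#' @export
bounded_xcorr <- function(trace, template, max_lag_s = NULL, fs = NULL) {
  if (inherits(template, "sine_template")) {
    fs <- fs %||% template$fs
    max_lag_s <- max_lag_s %||% (1 / (2 * template$freq_hz))
    template <- template$values
  }
  if (is.null(fs)) stop_pw("`fs` required when template is a plain vector")
  if (is.null(max_lag_s)) stop_pw("`max_lag_s` required")
  if (length(trace) != length(template))
    stop_pw("trace and template must share the same grid")
  L <- round(max_lag_s * fs)
  res <- xcorr_rows(trace, template, L)
  list(r = res$r[1], lag_s = res$lag[1] / fs)
}

#' Draw surrogate event latencies
#'
#' Uniform draws (with replacement by default) from the allowed time points —
#' the same N2/N3 artifact-free, window-interior region the true events come
#' from — matching the observed trial count.
#'
#' @param n_events number of surrogate events.
#' @param allowed_times_s candidate time points, seconds.
#' @param replace sample with replacement (default TRUE).
#' @return numeric vector of length `n_events`.
#' @export
surrogate_latencies <- function(n_events, allowed_times_s, replace = TRUE) {
  if (!length(allowed_times_s)) stop_pw("empty surrogate mask")
  allowed_times_s[sample.int(length(allowed_times_s), n_events,
                             replace = replace)]
}

# Shared statistic engine: event times -> epoch centers -> mean trace ->
# per-trial linear detrend -> bounded-lag correlation with the template.
# Per-trial detrending commutes with averaging (the detrend is one fixed
# linear projection), so it is applied once to the mean trace. `centers` is
# a B x n matrix of epoch-center sample indices: one row per (observed or
# surrogate) event set. Identical code path for observed and null statistics.
evoked_stat_engine <- function(signal, centers, npre, npost, IH, template, L) {
  B <- nrow(centers); n_ev <- ncol(centers)
  rel <- (-npre):npost
  flat <- as.integer(t(centers))                   # event-major within row
  idx <- outer(flat, as.integer(rel), "+")
  vals <- signal[idx]
  dim(vals) <- dim(idx)
  means <- rowsum(vals, rep(seq_len(B), each = n_ev), reorder = TRUE) / n_ev
  detr <- means %*% IH
  xcorr_rows(detr, template, L)
}

event_centers <- function(event_times_s, fs_signal, sync, npre, npost, n) {
  centers <- if (is.null(sync)) {
    round(event_times_s * fs_signal) + 1L
  } else {
    round(eeg_time_to_nirs_index(event_times_s, sync, strict = FALSE)) + 1L
  }
  as.integer(centers[!is.na(centers) & centers - npre >= 1L &
                       centers + npost <= n])
}

#' Random-latency permutation test of evoked phase-locking
#'
#' Computes the observed bounded-lag correlation between the event-locked
#' evoked trace and the heart-rate sine template, then rebuilds the identical
#' statistic for `n_perm` surrogate event sets whose latencies are drawn
#' uniformly from `allowed_times_s` (trial count matched; max over lags taken
#' exactly as for the observed statistic, which makes the test conservative).
#' The p-value is the plain proportion of surrogate correlations greater
#' than or equal to the observed one (it can be 0); `p_rule =
#' "conservative"` uses (k+1)/(n+1).
#'
#' @param signal raw signal vector (NIRS column, pooled AC, or ECG).
#' @param fs_signal its sampling rate, Hz.
#' @param event_times_s slow-wave landmark times, seconds, EEG clock.
#' @param template a [make_sine_template()].
#' @param allowed_times_s time points surrogate latencies are drawn from.
#' @param sync `sync_map` for NIRS signals; NULL for ECG.
#' @param n_perm number of surrogate datasets (default 5000; a warning is
#'   issued below 100).
#' @param max_lag_s lag bound, seconds; default half the template period.
#' @param window_s epoch window, seconds pre/post.
#' @param p_rule `"proportion"` (default) or `"conservative"`.
#' @param seed optional integer; set for exact reproducibility.
#' @return object of class `phase_lock_result`: `r`, `lag_s`, `p_value`,
#'   `null_r` (length `n_perm`), `n_perm`, `n_events`, `freq_hz`, `seed`.
#' @export
permutation_test <- function(signal, fs_signal, event_times_s, template,
                             allowed_times_s, sync = NULL, n_perm = 5000,
                             max_lag_s = NULL, window_s = c(3, 3),
                             p_rule = c("proportion", "conservative"),
                             seed = NULL) {
  p_rule <- match.arg(p_rule)
  stopifnot(inherits(template, "sine_template"))
  if (n_perm < 100) warning("fewer than 100 permutations: p-value is coarse")
  if (!is.null(seed)) set.seed(seed)
  max_lag_s <- max_lag_s %||% (1 / (2 * template$freq_hz))
  npre <- round(window_s[1] * fs_signal)
  npost <- round(window_s[2] * fs_signal)
  if (length(template$values) != npre + npost + 1L)
    stop_pw("template grid does not match the epoch window")
  L <- round(max_lag_s * fs_signal)
  n <- length(signal)
  obs_centers <- event_centers(event_times_s, fs_signal, sync, npre, npost, n)
  if (!length(obs_centers)) stop_pw("no usable events inside the recording")
  n_ev <- length(obs_centers)
  allowed_centers <- event_centers(allowed_times_s, fs_signal, sync, npre,
                                   npost, n)
  if (!length(allowed_centers)) stop_pw("empty surrogate mask")
  IH <- detrend_residual_maker(npre + npost + 1L)
  obs <- evoked_stat_engine(signal, matrix(obs_centers, nrow = 1L), npre,
                            npost, IH, template$values, L)
  null_r <- numeric(n_perm)
  block <- 100L
  done <- 0L
  while (done < n_perm) {
    b <- min(block, n_perm - done)
    cen <- matrix(allowed_centers[sample.int(length(allowed_centers),
                                             b * n_ev, replace = TRUE)],
                  nrow = b)
    null_r[(done + 1L):(done + b)] <-
      evoked_stat_engine(signal, cen, npre, npost, IH, template$values, L)$r
    done <- done + b
  }
  k <- sum(null_r >= obs$r[1])
  p <- if (p_rule == "proportion") k / n_perm else (k + 1) / (n_perm + 1)
  structure(list(r = obs$r[1], lag_s = obs$lag[1] / fs_signal, p_value = p,
                 null_r = null_r, n_perm = n_perm, n_events = n_ev,
                 freq_hz = template$freq_hz, max_lag_s = max_lag_s,
                 p_rule = p_rule, seed = seed),
            class = "phase_lock_result")
}

#' @export
print.phase_lock_result <- function(x, ...) {
  cat(sprintf(paste0("<phase_lock_result> r = %.3f at delay %.0f ms ",
                     "(nadir -> event), p = %.4g (%d permutations, %d events)\n"),
              x$r, 1000 * x$lag_s, x$p_value, x$n_perm, x$n_events))
  invisible(x)
}

#' @export
plot.phase_lock_result <- function(x, breaks = 30, ...) {
  graphics::hist(x$null_r, breaks = breaks, main = "surrogate correlations",
                 xlab = "max bounded-lag r",
                 xlim = range(c(x$null_r, x$r)), ...)
  graphics::abline(v = x$r, col = 2, lwd = 2)
  invisible(x)
}

#' Event times for a chosen slow-wave landmark
#'
#' @param waves a `slow_waves` table.
#' @param landmark one of `"onset"`, `"neg_peak"`, `"up_cross"`.
#' @return numeric vector of event times, seconds.
#' @export
lock_to_landmark <- function(waves, landmark = c("onset", "neg_peak",
                                                 "up_cross")) {
  landmark <- match.arg(landmark)
  switch(landmark,
         onset = waves$onset_s,
         neg_peak = waves$neg_peak_s,
         up_cross = waves$up_cross_s)
}
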