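#' Extract event-locked epochs from a signal
#'
#' Cuts a window of `window_s[1]` seconds before to `window_s[2]` seconds
#' after each event. Event times are given on the EEG clock; for a signal on
#' another clock (NIRS) supply a [build_sync_map()] and the event is placed
#' at the nearest sample of that signal (no resampling or interpolation of
#' the trace itself). Events whose window exceeds the recording are dropped
#' and counted.
#'
#' @param signal numeric vector.
#' @param fs_signal sampling rate of `signal`, Hz (nominal rate for NIRS).
#' @param event_times_s event times, seconds, EEG clock.
#' @param sync optional `sync_map`; NULL means the signal shares the EEG
#'   clock (ECG).
#' @param window_s length-2 numeric, seconds before/after (default 3/3).
#' @return object of class `epoch_set`: `trials` (events x samples matrix),
#'   `times_s` (within-epoch time axis, 0 at the event), `event_times_s`
#'   (events kept), `fs`, `n_dropped`.
#' @export
extract_epochs <- function(signal, fs_signal, event_times_s, sync = NULL,
                           window_s = c(3, 3)) {
  npre <- round(window_s[1] * fs_signal)
  npost <- round(window_s[2] * fs_signal)
  n <- length(signal)
  centers <- if (is.null(sync)) {
    round(event_times_s * fs_signal) + 1L
  } else {
    round(eeg_time_to_nirs_index(event_times_s, sync, strict = FALSE)) + 1L
  }
  ok <- !is.na(centers) & centers - npre >= 1L & centers + npost <= n
  if (!any(ok)) stop_pw("no usable events: every window exceeds the recording")
  centers <- centers[ok]
  rel <- (-npre):npost
  idx <- outer(centers, rel, "+")
  trials <- matrix(signal[idx], nrow = length(centers))
  structure(list(trials = trials, times_s = rel / fs_signal,
                 event_times_s = event_times_s[ok], fs = fs_signal,
                 n_dropped = sum(!ok)),
            class = "epoch_set")
}

# Projection matrix removing the least-squares line from a length-m row.
detrend_residual_maker <- function(m) {
  X <- cbind(1, seq_len(m))
  diag(m) - X %*% solve(crossprod(X), t(X))
}

#' Linearly detrend each trial
#'
#' Removes the per-trial least-squares line (intercept + slope), the only
#' preprocessing applied to NIRS epochs; it strips the slow instrumental
#' drift without touching the pulsation. Idempotent.
#'
#' @param epochs an `epoch_set`.
#' @return the `epoch_set` with detrended trials.
#' @export
detrend_trials <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  IH <- detrend_residual_maker(ncol(epochs$trials))
  epochs$trials <- epochs$trials %*% IH
  epochs
}

#' Average epochs into an evoked response
#'
#' Mean over all trials (optionally pooled over several `epoch_set`s with
#' identical windows, e.g. the eight brain-sensor AC channels). `noise_sd`
#' is the mean over time of the per-sample across-trial SD (option
#' `"per_trial"`: mean of per-trial SDs). The normalized trace
#' (`mean / noise_sd`) is for display only; statistics downstream use the
#' raw mean, and the bounded-lag Pearson statistic is invariant to the
#' normalization.
#'
#' @param epochs an `epoch_set` or a list of them to pool.
#' @param noise_method `"per_sample"` (default) or `"per_trial"`.
#' @return object of class `evoked_response`: `mean_trace`, `times_s`,
#'   `noise_sd`, `n_trials`, `normalized_trace`, `fs`.
#' @export
average_epochs <- function(epochs, noise_method = c("per_sample", "per_trial")) {
  noise_method <- match.arg(noise_method)
  if (inherits(epochs, "epoch_set")) epochs <- list(epochs)
  if (!length(epochs)) stop_pw("empty channel pool")
  stopifnot(all(vapply(epochs, inherits, TRUE, "epoch_set")))
  m <- ncol(epochs[[1]]$trials)
  if (!all(vapply(epochs, function(e) ncol(e$trials) == m, TRUE)))
    stop_pw("pooled epoch sets must share the same window")
  trials <- do.call(rbind, lapply(epochs, `[[`, "trials"))
  mean_trace <- colMeans(trials)
  noise_sd <- if (nrow(trials) > 1L) {
    if (noise_method == "per_sample") mean(apply(trials, 2L, sd))
    else mean(apply(trials, 1L, sd))
  } else 0
  structure(list(mean_trace = mean_trace, times_s = epochs[[1]]$times_s,
                 noise_sd = noise_sd, n_trials = nrow(trials),
                 normalized_trace = if (noise_sd > 0) mean_trace / noise_sd
                                    else NULL,
                 fs = epochs[[1]]$fs),
            class = "evoked_response")
}

#' @export
print.evoked_response <- function(x, ...) {
  cat(sprintf("<evoked_response> %d trials, %d samples @ %g Hz, noise_sd %.4g\n",
              x$n_trials, length(x$mean_trace), x$fs, x$noise_sd))
  invisible(x)
}

#' @export
plot.evoked_response <- function(x, normalized = FALSE, ...) {
  y <- if (normalized && !is.null(x$normalized_trace)) x$normalized_trace
       else x$mean_trace
  graphics::plot(x$times_s, y, type = "l", xlab = "time from event (s)",
                 ylab = if (normalized) "mean / noise SD" else "mean signal",
                 ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
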