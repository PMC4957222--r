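`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pw <- function(fmt, ..., class = "pulsewave_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

check_scalar_num <- function(x, name, positive = TRUE, ge_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_pw("`%s` must be a finite numeric scalar", name)
  if (ge_zero && x < 0) stop_pw("`%s` must be >= 0", name)
  if (positive && !ge_zero && x <= 0) stop_pw("`%s` must be > 0", name)
  invisible(x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (two-pass) IIR filtering so that landmark timings are not
#' shifted by the filter's phase response. Used for the 1-4 Hz slow-wave band
#' and the ECG band splits.
#'
#' @param x numeric vector or matrix (columns filtered independently).
#' @param band length-2 numeric, band edges in Hz.
#' @param fs sampling rate in Hz.
#' @param order Butterworth prototype order per edge (default 2).
#' @return filtered object of the same shape as `x`.
#' @export
bandpass <- function(x, band, fs, order = 2L) {
  if (length(band) != 2L || !all(is.finite(band)) || band[1] <= 0 ||
      band[2] <= band[1])
    stop_pw("`band` must be an ordered positive pair of frequencies")
  if (band[2] >= fs / 2)
    stop_pw("band upper edge %.3g Hz is at or above Nyquist (%.3g Hz)",
            band[2], fs / 2)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  core <- function(col) {
    n <- length(col)
    # odd-reflection padding, ~10 cycles of the low band edge
    np <- min(n - 1L, round(10 * fs / band[1]))
    pre <- 2 * col[1] - col[(np + 1L):2L]
    post <- 2 * col[n] - col[(n - 1L):(n - np)]
    y <- iir_apply(bf$b, bf$a, c(pre, col, post))
    y <- rev(iir_apply(bf$b, bf$a, rev(y)))      # second pass: zero phase
    y[(np + 1L):(np + n)]
  }
  if (is.matrix(x)) apply(x, 2L, core) else core(x)
}

# Direct-form IIR pass (identical output to signal::filter, but without the
# time-series class overhead): MA part by one-sided convolution, AR part by
# the recursive filter.
iir_apply <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1L), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[-seq_len(nb - 1L)]
  as.numeric(stats::filter(v, -a[-1], method = "recursive"))
}
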