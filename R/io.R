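#' Write / read the raw NIRS table
#'
#' Tab-separated text, rows = samples, 48 data columns in the documented
#' sensor-major order (see [nirs_layout()]).
#'
#' @param path file path.
#' @param tab data.frame with the 48 NIRS columns.
#' @return `path` invisibly (writer); annotated data.frame (reader).
#' @export
write_nirs_table <- function(path, tab) {
  lay <- nirs_layout()
  if (!identical(names(tab), lay$name))
    stop_pw("NIRS table columns must follow the documented 48-column layout")
  write.table(format(tab, digits = 8, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param fs_nominal nominal sampling rate attached as attribute `fs_nominal`.
#' @rdname write_nirs_table
#' @export
read_nirs_table <- function(path, fs_nominal = NA_real_) {
  if (!file.exists(path)) stop_pw("file not found: %s", path)
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  lay <- nirs_layout()
  if (ncol(tab) != nrow(lay))
    stop_pw(paste0("expected 48 NIRS columns (2 sensors x {DC,AC,PD} x 4 ",
                   "distances x 2 wavelengths), got %d"), ncol(tab))
  names(tab) <- lay$name
  attr(tab, "layout") <- lay
  attr(tab, "fs_nominal") <- fs_nominal
  tab
}

#' Write / read a hypnogram and its artifact list
#'
#' Hypnogram: CSV with `epoch_index` (0-based, 30-s epochs) and `stage`
#' (W/N1/N2/N3/REM). Artifacts: CSV with `start_s`, `end_s`, `kind`
#' (half-open intervals on the EEG clock).
#'
#' @param path file path.
#' @param hyp,art data.frames as described.
#' @export
write_hypnogram <- function(path, hyp) {
  stopifnot(all(c("epoch_index", "stage") %in% names(hyp)))
  write.table(hyp, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  hyp <- read.table(path, header = TRUE, sep = ",")
  bad <- setdiff(unique(hyp$stage), c("W", "N1", "N2", "N3", "REM"))
  if (length(bad)) stop_pw("unknown stage label(s): %s", paste(bad, collapse = ","))
  hyp
}

#' @rdname write_hypnogram
#' @export
write_artifacts <- function(path, art) {
  write.table(art, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_artifacts <- function(path) {
  art <- read.table(path, header = TRUE, sep = ",",
                    colClasses = c("numeric", "numeric", "character"))
  names(art) <- c("start_s", "end_s", "kind")
  art
}

#' Write a synthetic recording (and its truth) to disk
#'
#' EDF for EEG/ECG (+ trigger annotations), TSV for NIRS, CSVs for the
#' hypnogram and artifacts, JSON sidecar for the simulation ground truth.
#'
#' @param rec an `sw_recording`.
#' @param dir output directory (created if needed).
#' @param truth optional `sim_truth` to save alongside.
#' @return `dir` invisibly.
#' @export
write_recording <- function(rec, dir, truth = NULL) {
  stopifnot(inherits(rec, "sw_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_psg(file.path(dir, "psg.edf"), rec$eeg, rec$ecg, rec$fs_eeg,
            triggers = rec$triggers)
  write_nirs_table(file.path(dir, "nirs.tsv"), rec$nirs)
  write_hypnogram(file.path(dir, "hypnogram.csv"), rec$hypnogram)
  write_artifacts(file.path(dir, "artifacts.csv"), rec$artifacts)
  meta <- list(fs_nirs_nominal = rec$fs_nirs_nominal)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(truth)) {
    tr <- truth[setdiff(names(truth), "config")]
    tr$config <- unclass(truth$config)
    jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  psg <- read_psg(file.path(dir, "psg.edf"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  nirs <- read_nirs_table(file.path(dir, "nirs.tsv"),
                          fs_nominal = meta$fs_nirs_nominal)
  structure(list(eeg = psg$eeg, ecg = psg$ecg, fs_eeg = psg$fs,
                 nirs = nirs, fs_nirs_nominal = meta$fs_nirs_nominal,
                 hypnogram = read_hypnogram(file.path(dir, "hypnogram.csv")),
                 artifacts = read_artifacts(file.path(dir, "artifacts.csv")),
                 triggers = psg$triggers),
            class = "sw_recording")
}

#' Build the EEG-to-NIRS time mapping from the trigger pair
#'
#' The NIRS device marks its first and last sample on the EEG clock via a
#' trigger cable. A linear map `t_eeg = intercept + slope * index` (0-based
#' sample index) absorbs any deviation of either device's real sampling rate
#' from nominal.
#'
#' @param trigger_start_s,trigger_end_s trigger times on the EEG clock.
#' @param n_nirs_samples number of rows in the NIRS table.
#' @param fs_nominal nominal NIRS rate, Hz; a deviation of the implied rate
#'   beyond 1% triggers a warning (not an error).
#' @return object of class `sync_map`: `slope` (s/sample), `intercept` (s),
#'   `n_samples`, `fs_nominal`, `fs_implied`.
#' @export
build_sync_map <- function(trigger_start_s, trigger_end_s, n_nirs_samples,
                           fs_nominal) {
  if (trigger_end_s <= trigger_start_s)
    stop_pw("trigger_end must be after trigger_start")
  if (n_nirs_samples < 2L) stop_pw("need at least 2 NIRS samples")
  slope <- (trigger_end_s - trigger_start_s) / (n_nirs_samples - 1)
  fs_implied <- 1 / slope
  if (abs(fs_implied - fs_nominal) / fs_nominal > 0.01)
    warning(sprintf("implied NIRS rate %.4f Hz deviates >1%% from nominal %g Hz",
                    fs_implied, fs_nominal))
  structure(list(slope = slope, intercept = trigger_start_s,
                 n_samples = as.integer(n_nirs_samples),
                 fs_nominal = fs_nominal, fs_implied = fs_implied),
            class = "sync_map")
}

#' Map EEG times to fractional NIRS sample indices (and back)
#'
#' Indices are 0-based: EEG time `trigger_start` maps to index 0 and
#' `trigger_end` to `n_samples - 1`. The two functions are exact inverses.
#'
#' @param t_eeg time(s) on the EEG clock, seconds.
#' @param sync a [build_sync_map()] result.
#' @param strict error on out-of-range inputs (default); otherwise NA.
#' @return fractional index / EEG seconds.
#' @export
eeg_time_to_nirs_index <- function(t_eeg, sync, strict = TRUE) {
  stopifnot(inherits(sync, "sync_map"))
  idx <- (t_eeg - sync$intercept) / sync$slope
  out <- idx < -1e-9 | idx > sync$n_samples - 1 + 1e-9
  if (any(out)) {
    if (strict)
      stop_pw("%d event time(s) outside the NIRS recording span", sum(out))
    idx[out] <- NA_real_
  }
  idx
}

#' @param index fractional 0-based NIRS sample index.
#' @rdname eeg_time_to_nirs_index
#' @export
nirs_index_to_eeg_time <- function(index, sync) {
  stopifnot(inherits(sync, "sync_map"))
  sync$intercept + index * sync$slope
}

#' Per-sample stage mask on the EEG clock
#'
#' TRUE exactly where the hypnogram stage is one of `stages` and, optionally,
#' outside every artifact/arousal interval. Epoch `k` covers the half-open
#' time interval `[30k, 30k + 30)`; artifact intervals are half-open too.
#'
#' @param hypnogram data.frame `epoch_index`, `stage`.
#' @param n_samples number of EEG samples the mask must cover.
#' @param fs EEG sampling rate, Hz.
#' @param stages character vector of stage labels to include.
#' @param artifacts optional data.frame `start_s`, `end_s` to exclude.
#' @return logical vector of length `n_samples`.
#' @export
stage_mask <- function(hypnogram, n_samples, fs, stages = c("N2", "N3"),
                       artifacts = NULL) {
  known <- c("W", "N1", "N2", "N3", "REM")
  if (!all(stages %in% known))
    stop_pw("unknown stage label(s): %s",
            paste(setdiff(stages, known), collapse = ", "))
  mask <- logical(n_samples)
  t_of <- function(s) (s - 1) / fs           # sample i sits at time (i-1)/fs
  for (r in seq_len(nrow(hypnogram))) {
    if (!(hypnogram$stage[r] %in% stages)) next
    e <- hypnogram$epoch_index[r]
    i0 <- floor(30 * e * fs) + 1L
    i1 <- min(floor(30 * (e + 1) * fs), n_samples)
    if (i0 <= i1) mask[i0:i1] <- TRUE
  }
  if (!is.null(artifacts) && nrow(artifacts)) {
    tt <- t_of(seq_len(n_samples))
    for (r in seq_len(nrow(artifacts)))
      mask[tt >= artifacts$start_s[r] & tt < artifacts$end_s[r]] <- FALSE
  }
  mask
}

#' Write / read a detected wave list
#'
#' CSV with one row per slow wave (onset, negative peak, upward
#' zero-crossing, slope, participating channels).
#'
#' @param path file path.
#' @param waves a `slow_waves` table.
#' @export
write_waves <- function(path, waves) {
  write.table(as.data.frame(waves), path, sep = ",", quote = TRUE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_waves
#' @export
read_waves <- function(path) {
  w <- read.table(path, header = TRUE, sep = ",")
  class(w) <- c("slow_waves", "data.frame")
  w
}

#' Serialize a phase-locking result to JSON
#'
#' Writes `r`, the phase delay, the p-value and the test's bookkeeping; the
#' surrogate null distribution is included when `keep_null = TRUE`.
#'
#' @param path file path.
#' @param result a `phase_lock_result`.
#' @param keep_null include the full null distribution (default FALSE).
#' @export
write_phase_lock <- function(path, result, keep_null = FALSE) {
  stopifnot(inherits(result, "phase_lock_result"))
  out <- result[c("r", "lag_s", "p_value", "n_perm", "n_events", "freq_hz",
                  "max_lag_s", "p_rule", "seed")]
  if (keep_null) out$null_r <- result$null_r
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
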