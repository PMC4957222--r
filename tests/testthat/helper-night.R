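# Shared fixture machinery: run the brain-AC onset-locked permutation
# statistic on a simulated night, via the same public functions a user
# would call.
brain_ac_signal <- function(rec) {
  lay <- nirs_layout()
  rowMeans(rec$nirs[, lay$name[lay$sensor == "brain" & lay$measure == "AC"]])
}

night_phase_lock <- function(rec, waves, n_perm = 500, seed = 1,
                             landmark = "onset", signal = NULL,
                             fs_signal = NULL, use_sync = TRUE) {
  beats <- detect_r_peaks(rec$ecg, rec$fs_eeg)
  hr <- mean_heart_rate(beats, rec$hypnogram)
  sync <- build_sync_map(rec$triggers[["start"]], rec$triggers[["end"]],
                         nrow(rec$nirs), rec$fs_nirs_nominal)
  mask <- stage_mask(rec$hypnogram, nrow(rec$eeg), rec$fs_eeg)
  allowed <- (which(mask) - 1) / rec$fs_eeg
  if (is.null(signal)) {
    signal <- brain_ac_signal(rec)
    fs_signal <- rec$fs_nirs_nominal
  }
  tpl <- make_sine_template(hr$mean_hz, c(3, 3), fs_signal)
  permutation_test(signal, fs_signal, lock_to_landmark(waves, landmark),
                   tpl, allowed, sync = if (use_sync) sync else NULL,
                   n_perm = n_perm, seed = seed)
}
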