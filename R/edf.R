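# Minimal EDF(+C) writer/reader: 16-bit samples, 1-second data records, one
# "EDF Annotations" channel carrying the NIRS start/end trigger marks as
# time-stamped annotation lists (TALs). Covers exactly what the pipeline
# needs from the format; not a general-purpose EDF implementation.

pad_ascii <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = " ")
}

edf_num <- function(x, width) pad_ascii(formatC(x, format = "fg", digits = 7), width)

#' Write EEG + ECG channels to an EDF+ file
#'
#' Six EEG channels (microvolts) and one ECG channel (millivolts) are stored
#' as 16-bit integers in 1-second records; trigger times are written as
#' annotations `nirs_start` / `nirs_end` in an EDF Annotations channel.
#' Signal length is truncated to a whole number of seconds.
#'
#' @param path output file path.
#' @param eeg samples x 6 matrix with channel names, microvolts.
#' @param ecg numeric vector, millivolts, same length/rate as the EEG.
#' @param fs sampling rate in Hz (integer).
#' @param triggers optional named numeric `c(start=, end=)`, seconds.
#' @param phys_range_eeg,phys_range_ecg physical scaling ranges.
#' @return `path`, invisibly.
#' @export
write_psg <- function(path, eeg, ecg, fs, triggers = NULL,
                      phys_range_eeg = c(-2000, 2000),
                      phys_range_ecg = c(-6, 6)) {
  stopifnot(is.matrix(eeg), ncol(eeg) == 6L, length(ecg) == nrow(eeg))
  fs <- as.integer(fs)
  n_rec <- nrow(eeg) %/% fs
  if (n_rec < 1L) stop_pw("signal shorter than one 1-s data record")
  labels <- c(paste("EEG", colnames(eeg)), "ECG", "EDF Annotations")
  dims <- c(rep("uV", 6), "mV", "")
  pmin_ <- c(rep(phys_range_eeg[1], 6), phys_range_ecg[1], -1)
  pmax_ <- c(rep(phys_range_eeg[2], 6), phys_range_ecg[2], 1)
  dmin_ <- rep(-32768, 8); dmax_ <- rep(32767, 8)
  spr <- c(rep(fs, 7), 60L)              # 60 2-byte samples = 120 bytes of TALs
  ns <- 8L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_ascii("0", 8), pad_ascii("X X X X", 80),
    pad_ascii("Startdate X X X X", 80),
    "01.01.00", "00.00.00",
    pad_ascii(256 * (ns + 1L), 8), pad_ascii("EDF+C", 44),
    pad_ascii(n_rec, 8), pad_ascii("1", 8), pad_ascii(ns, 4))
  writeChar(hdr, con, eos = NULL)
  for (field in list(vapply(labels, pad_ascii, "", width = 16),
                     rep(pad_ascii("", 80), ns),
                     vapply(dims, pad_ascii, "", width = 8),
                     vapply(pmin_, edf_num, "", width = 8),
                     vapply(pmax_, edf_num, "", width = 8),
                     vapply(dmin_, edf_num, "", width = 8),
                     vapply(dmax_, edf_num, "", width = 8),
                     rep(pad_ascii("", 80), ns),
                     vapply(spr, pad_ascii, "", width = 8),
                     rep(pad_ascii("", 32), ns)))
    writeChar(paste(field, collapse = ""), con, eos = NULL)

  to_dig <- function(x, pmin, pmax) {
    d <- round((x - pmin) / (pmax - pmin) * 65535 - 32768)
    as.integer(pmin(pmax(d, -32768), 32767))
  }
  tal_bytes <- function(rec) {
    b <- c(charToRaw(sprintf("+%d\x14\x14", rec - 1L)), as.raw(0))
    if (rec == 1L && !is.null(triggers)) {
      for (nm in names(triggers))
        b <- c(b, charToRaw(sprintf("+%.6f\x14nirs_%s\x14", triggers[[nm]],
                                    nm)), as.raw(0))
    }
    if (length(b) > 120L) stop_pw("annotation record overflow")
    c(b, raw(120L - length(b)))
  }
  for (rec in seq_len(n_rec)) {
    sl <- ((rec - 1L) * fs + 1L):(rec * fs)
    for (ch in 1:6)
      writeBin(to_dig(eeg[sl, ch], pmin_[ch], pmax_[ch]), con, size = 2L,
               endian = "little")
    writeBin(to_dig(ecg[sl], pmin_[7], pmax_[7]), con, size = 2L,
             endian = "little")
    writeBin(tal_bytes(rec), con)
  }
  invisible(path)
}

#' Read a PSG EDF file written for this pipeline
#'
#' Parses the EDF header, converts 16-bit samples back to physical units and
#' extracts `nirs_start` / `nirs_end` trigger annotations.
#'
#' @param path EDF file path.
#' @param require_channels channel labels that must be present (error if not).
#' @return list: `eeg` (samples x 6 matrix, microvolts), `ecg` (millivolts),
#'   `fs` (Hz), `annotations` (data.frame onset_s/text), `triggers`
#'   (named numeric, possibly empty).
#' @export
read_psg <- function(path,
                     require_channels = c("F3", "F4", "C3", "C4", "O1", "O2")) {
  if (!file.exists(path)) stop_pw("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) readChar(con, nchars, useBytes = TRUE)
  version <- trimws(rd(8))
  if (version != "0") stop_pw("corrupt EDF header (version field '%s')", version)
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L || is.na(n_rec)) stop_pw("corrupt EDF header")
  fields <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- fields(16); fields(80); dims <- fields(8)
  pmin_ <- as.numeric(fields(8)); pmax_ <- as.numeric(fields(8))
  dmin_ <- as.numeric(fields(8)); dmax_ <- as.numeric(fields(8))
  fields(80); spr <- as.integer(fields(8)); fields(32)
  seek(con, hdr_bytes)

  ann_ch <- which(labels == "EDF Annotations")
  sig <- lapply(seq_len(ns), function(i)
    if (i %in% ann_ch) raw(0) else numeric(n_rec * spr[i]))
  ann_raw <- raw(0)
  for (rec in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (i %in% ann_ch) {
        ann_raw <- c(ann_raw, readBin(con, "raw", 2L * spr[i]))
      } else {
        d <- readBin(con, "integer", spr[i], size = 2L, signed = TRUE,
                     endian = "little")
        phys <- pmin_[i] + (d + 32768) / 65535 * (pmax_[i] - pmin_[i])
        sig[[i]][((rec - 1L) * spr[i] + 1L):(rec * spr[i])] <- phys
      }
    }
  }
  # parse TALs: "+onset[\x15dur]\x14text1\x14text2...\x14\x00"
  ann <- data.frame(onset_s = numeric(0), text = character(0))
  nul <- which(ann_raw == as.raw(0))
  starts <- c(1L, head(nul, -1) + 1L)
  chunks <- vapply(seq_along(nul), function(k) {
    if (nul[k] - 1L < starts[k]) return("")
    rawToChar(ann_raw[starts[k]:(nul[k] - 1L)])
  }, "")
  for (tal in chunks) {
    if (!nzchar(tal)) next
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2L || !nzchar(parts[2])) next
    onset <- suppressWarnings(as.numeric(sub("\x15.*", "", parts[1])))
    for (txt in parts[-1])
      if (nzchar(txt))
        ann <- rbind(ann, data.frame(onset_s = onset, text = txt))
  }
  eeg_idx <- match(paste("EEG", require_channels), labels)
  if (anyNA(eeg_idx)) {
    miss <- require_channels[is.na(eeg_idx)]
    stop_pw("missing required channel(s): %s", paste(miss, collapse = ", "))
  }
  ecg_idx <- match("ECG", labels)
  if (is.na(ecg_idx)) stop_pw("missing required channel(s): ECG")
  eeg <- do.call(cbind, sig[eeg_idx])
  colnames(eeg) <- require_channels
  trig <- setNames(ann$onset_s[grepl("^nirs_", ann$text)],
                   sub("^nirs_", "", ann$text[grepl("^nirs_", ann$text)]))
  list(eeg = eeg, ecg = sig[[ecg_idx]], fs = spr[eeg_idx[1]] / rec_dur,
       annotations = ann, triggers = trig)
}
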