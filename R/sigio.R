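#' Band-pass preprocess a raw EEG recording
#'
#' Applies the standard 0.5-50 Hz third-order Butterworth band-pass,
#' zero-phase (forward-backward), and sets the `filtered` flag. Refuses to
#' filter twice.
#'
#' @param raw an [eeg_recording()] with `rate >= 128` Hz.
#' @return the filtered [eeg_recording()].
#' @export
preprocess_eeg <- function(raw) {
  stopifnot(inherits(raw, "eeg_recording"))
  if (raw$filtered) stop("recording is already band-pass filtered")
  if (raw$rate < 128) stop("EEG rate must be >= 128 Hz")
  if (length(raw$samples) == 0)
    return(eeg_recording(numeric(0), raw$rate, raw$start_time,
                         filtered = TRUE))
  bf <- signal::butter(3, c(0.5, 50) / (raw$rate / 2), type = "pass")
  eeg_recording(signal::filtfilt(bf, raw$samples), raw$rate, raw$start_time,
                filtered = TRUE)
}

# time (seconds, stream clock) at which the rectified envelope first exceeds
# `k` robust SDs above the median
first_artifact_time <- function(samples, rate, start_time, k = 8) {
  env <- abs(samples - stats::median(samples))
  thr <- stats::median(env) + k * stats::mad(env)
  idx <- which(env > thr)
  if (length(idx) == 0) return(NA_real_)
  start_time + (idx[1] - 1L) / rate
}

#' Estimate the constant offset between the intracortical and EEG clocks
#'
#' The sync routine places a high-amplitude square-wave impulse on the
#' intracortical marker stream and three tap deflections on the EEG. The
#' offset aligning the impulse with the first tap is estimated from the
#' first supra-threshold sample of each rectified envelope, to the nearest
#' sample. Adding the returned offset to intracortical times yields EEG
#' times.
#'
#' @param neural_marker list with `samples`, `rate`, `start_time`: the
#'   intracortical marker stream containing the square-wave impulse.
#' @param eeg an [eeg_recording()] containing the tap artifact.
#' @param threshold_k detection threshold in robust SDs of the envelope.
#' @return offset in seconds (`eeg_time - neural_time`).
#' @export
align_clocks <- function(neural_marker, eeg, threshold_k = 8) {
  t_n <- first_artifact_time(neural_marker$samples, neural_marker$rate,
                             neural_marker$start_time, threshold_k)
  t_e <- first_artifact_time(eeg$samples, eeg$rate, eeg$start_time,
                             threshold_k)
  if (is.na(t_n)) stop("no sync artifact found on the neural marker stream")
  if (is.na(t_e)) stop("no sync artifact found on the EEG stream")
  t_e - t_n
}

# ---------------------------------------------------------------------------
# Directory containers: one directory per object, numeric datasets as CSV
# (full round-trip precision via data.table) plus a JSON metadata file.
# ---------------------------------------------------------------------------

#' Write a feature series to a directory container
#'
#' Layout: `<dir>/meta.json` (bin width, start time, channel/feature
#' metadata) and `<dir>/features.csv` (features x bins, one row per
#' feature). Values round-trip losslessly.
#'
#' @param fs a [feature_series()].
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_feature_series <- function(fs, dir) {
  stopifnot(inherits(fs, "feature_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(type = "feature_series", bin_width = fs$bin_width,
         start_time = fs$start_time, channel_meta = fs$channel_meta,
         feature_meta = fs$feature_meta),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  data.table::fwrite(data.table::as.data.table(fs$values),
                     file.path(dir, "features.csv"))
  invisible(dir)
}

#' Read a feature series from a directory container
#' @param dir directory written by [write_feature_series()].
#' @return a [feature_series()].
#' @export
read_feature_series <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  vals <- as.matrix(data.table::fread(file.path(dir, "features.csv")))
  dimnames(vals) <- NULL
  feature_series(vals, meta$bin_width, meta$start_time,
                 channel_meta = as.data.frame(meta$channel_meta),
                 feature_meta = as.data.frame(meta$feature_meta))
}

#' Write / read an EEG recording container
#' @param eeg an [eeg_recording()].
#' @param dir target directory.
#' @return `dir` (write) or an [eeg_recording()] (read).
#' @export
write_eeg <- function(eeg, dir) {
  stopifnot(inherits(eeg, "eeg_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(type = "eeg_recording", rate = eeg$rate,
         start_time = eeg$start_time, filtered = eeg$filtered),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  data.table::fwrite(data.table::data.table(samples = eeg$samples),
                     file.path(dir, "eeg.csv"))
  invisible(dir)
}

#' @rdname write_eeg
#' @export
read_eeg <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  x <- data.table::fread(file.path(dir, "eeg.csv"))
  eeg_recording(x$samples, meta$rate, meta$start_time, meta$filtered)
}

#' Write / read an event table as CSV (RFC 4180, header mandatory)
#' @param events an [event_table()].
#' @param path CSV file path.
#' @return `path` (write) or an [event_table()] (read).
#' @export
write_event_table <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time", "duration", "kind") %in% names(df)))
    stop("event CSV must carry a header with time, duration, kind columns")
  extra <- df[setdiff(names(df), c("time", "duration", "kind", "label",
                                   "success"))]
  do.call(event_table,
          c(list(time = df$time, duration = df$duration, kind = df$kind,
                 label = if ("label" %in% names(df)) df$label else NA,
                 success = if ("success" %in% names(df)) df$success else NA),
            as.list(extra)))
}

#' Write / read a session configuration as YAML
#' @param cfg a `synth_config`.
#' @param path YAML file path.
#' @return `path` (write) or a `synth_config` (read).
#' @export
write_config <- function(cfg, path) {
  raw <- unclass(cfg)
  # named atomic vectors serialize as YAML maps only via lists
  raw$sws_cycle <- as.list(raw$sws_cycle)
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$replay_schedule))
    raw$replay_schedule <- as.data.frame(raw$replay_schedule)
  if (!is.null(raw$sws_cycle)) raw$sws_cycle <- unlist(raw$sws_cycle)
  do.call(synth_config, raw)
}

# ---------------------------------------------------------------------------
# Minimal EDF (European Data Format) reader/writer for real-EEG ingestion.
# EDF stores int16 samples with a per-signal linear calibration; the writer
# exists to build test fixtures in code and is intentionally minimal
# (one data record per second, continuous recording).
# ---------------------------------------------------------------------------

#' Read a single-channel EDF file into an EEG recording
#'
#' Minimal EDF reader: parses the fixed-layout header and the int16 data
#' records of the first signal, applying the physical/digital calibration.
#'
#' @param path EDF file path.
#' @param signal index of the signal to read (default 1).
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path, signal = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- hdr(8)
  if (version != "0") stop("not an EDF file (version field != '0')")
  hdr(80 + 80 + 8 + 8)                      # patient, recording, date, time
  n_header <- as.integer(hdr(8))
  hdr(44)                                   # reserved
  n_rec <- as.integer(hdr(8))
  rec_dur <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  if (signal > ns) stop("signal index out of range")
  fld <- function(w) vapply(seq_len(ns), function(i) hdr(w), "")
  fld(16)                                   # labels
  fld(80); fld(8)                           # transducer, unit
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)                                   # prefiltering
  spr <- as.integer(fld(8))                 # samples per record
  fld(32)                                   # reserved
  seek(con, n_header)
  out <- numeric(n_rec * spr[signal])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dat <- readBin(con, "integer", n = spr[s], size = 2, endian = "little")
      if (s == signal)
        out[((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
          phys_min[s] + gain[s] * (dat - dig_min[s])
    }
  }
  eeg_recording(out, rate = spr[signal] / rec_dur, start_time = 0)
}

#' Write an EEG recording as a minimal single-signal EDF file
#'
#' Companion to [read_edf()] for building fixtures programmatically; uses
#' 1 s data records and a symmetric physical range covering the data.
#'
#' @param eeg an [eeg_recording()]; length must be a whole number of seconds.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(eeg, path) {
  fs <- as.integer(round(eeg$rate))
  n_rec <- length(eeg$samples) %/% fs
  if (n_rec * fs != length(eeg$samples))
    stop("EDF writer requires a whole number of 1 s records")
  pmax_ <- max(1e-6, max(abs(eeg$samples)))
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, w)
    writeBin(charToRaw(formatC(x, width = w, flag = "-")), con)
  put("0", 8); put("synthetic", 80); put("synthetic", 80)
  put("01.01.26", 8); put("00.00.00", 8)
  put(as.character(256 + 256), 8)           # header bytes for 1 signal
  put("", 44); put(as.character(n_rec), 8); put("1", 8); put("1", 4)
  put("EEG", 16); put("synthetic", 80); put("uV", 8)
  put(formatC(-pmax_, format = "g", digits = 6), 8)
  put(formatC(pmax_, format = "g", digits = 6), 8)
  put("-32768", 8); put("32767", 8); put("", 80)
  put(as.character(fs), 8); put("", 32)
  dig <- as.integer(round(eeg$samples / pmax_ * 32767))
  writeBin(dig, con, size = 2, endian = "little")
  invisible(path)
}
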