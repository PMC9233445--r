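#' Binned neural feature time series
#'
#' Container for per-channel binned neural features on a uniform time grid.
#' Each recording channel contributes two features per bin: mean spike-band
#' (250-5000 Hz) power (`"sbp"`) and the number of threshold crossing events
#' (`"tx"`). Rows of `values` are features, columns are 20 ms bins.
#'
#' @param values numeric matrix, features x bins.
#' @param bin_width bin width in seconds (default 0.02).
#' @param start_time time of the first bin's left edge, seconds, on the
#'   intracortical clock.
#' @param channel_meta data.frame with one row per channel, columns
#'   `channel` and `array` (`"medial"` or `"lateral"`). If `NULL`, channels
#'   are split half medial, half lateral (medial first).
#' @param feature_meta data.frame with one row per feature, columns
#'   `feature`, `channel`, `kind` (`"sbp"` or `"tx"`). If `NULL`, features
#'   are assumed interleaved per channel: sbp then tx.
#'
#' @return An object of class `feature_series`.
#' @export
feature_series <- function(values, bin_width = 0.02, start_time = 0,
                           channel_meta = NULL, feature_meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (features x bins)")
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("`bin_width` must be a single positive number")
  n_feat <- nrow(values)
  if (n_feat %% 2L != 0L)
    stop("feature count must be even (two features per channel)")
  n_chan <- n_feat %/% 2L
  if (is.null(channel_meta)) {
    half <- ceiling(n_chan / 2)
    channel_meta <- data.frame(
      channel = seq_len(n_chan),
      array = rep(c("medial", "lateral"), c(half, n_chan - half)),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(feature_meta)) {
    feature_meta <- data.frame(
      feature = seq_len(n_feat),
      channel = rep(seq_len(n_chan), each = 2L),
      kind = rep(c("sbp", "tx"), n_chan),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(nrow(channel_meta) == n_chan, nrow(feature_meta) == n_feat)
  structure(
    list(values = values, bin_width = bin_width, start_time = start_time,
         channel_meta = channel_meta, feature_meta = feature_meta),
    class = "feature_series"
  )
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf(
    "<feature_series> %d features (%d channels), %d bins of %g s, t0 = %g s\n",
    nrow(x$values), nrow(x$channel_meta), ncol(x$values), x$bin_width,
    x$start_time))
  invisible(x)
}

#' Bin left-edge times of a feature or trajectory series
#'
#' @param x a `feature_series`, `trajectory_series` or `correlation_series`.
#' @return numeric vector of bin start times in seconds.
#' @export
bin_times <- function(x) {
  n <- if (inherits(x, "feature_series")) ncol(x$values) else length(x$x %||% x$cc_x)
  x$start_time + (seq_len(n) - 1L) * x$bin_width
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract a time window from a feature series
#'
#' @param fs a `feature_series`.
#' @param from,to window limits in seconds (`from` inclusive, `to` exclusive).
#' @return a `feature_series` restricted to bins starting in `[from, to)`.
#' @export
fs_window <- function(fs, from, to) {
  tt <- bin_times(fs)
  keep <- tt >= from - 1e-9 & tt < to - 1e-9
  if (!any(keep)) stop("requested window contains no bins")
  feature_series(fs$values[, keep, drop = FALSE], fs$bin_width,
                 start_time = tt[which(keep)[1L]],
                 channel_meta = fs$channel_meta, feature_meta = fs$feature_meta)
}

#' Scalp EEG recording
#'
#' @param samples numeric vector of EEG samples (microvolts).
#' @param rate sampling rate in Hz (default 512).
#' @param start_time time of the first sample in seconds, on the EEG clock.
#' @param filtered logical flag: has the 0.5-50 Hz band-pass been applied?
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, rate = 512, start_time = 0,
                          filtered = FALSE) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a single positive number")
  if (!is.numeric(samples)) stop("`samples` must be numeric")
  structure(
    list(samples = as.numeric(samples), rate = rate, start_time = start_time,
         filtered = isTRUE(filtered)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples at %g Hz (%.1f s), t0 = %g s, %s\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              x$start_time,
              if (x$filtered) "band-passed 0.5-50 Hz" else "raw"))
  invisible(x)
}

#' Typed, timestamped event table
#'
#' Rows describe trials, STCEs, ripples, ground-truth injections or sync
#' marks. Extra columns (e.g. cued target coordinates during calibration,
#' injected tau and amplitude) are preserved.
#'
#' @param time event onsets in seconds (sorted, non-negative).
#' @param duration event durations in seconds (non-negative).
#' @param kind one of `"trial"`, `"stce"`, `"ripple"`, `"injected"`, `"sync"`.
#' @param label free-text label (e.g. `"target"`, `"distractor"`).
#' @param success optional logical success flag.
#' @param ... further columns, recycled to the table length.
#' @return a data.frame with class `event_table`.
#' @export
event_table <- function(time = numeric(0), duration = 0, kind = character(0),
                        label = NA_character_, success = NA, ...) {
  n <- length(time)
  kinds_ok <- c("trial", "stce", "ripple", "injected", "sync")
  df <- data.frame(
    time = as.numeric(time),
    duration = rep_len(as.numeric(duration), n),
    kind = rep_len(as.character(kind), n),
    label = rep_len(as.character(label), n),
    success = rep_len(success, n),
    stringsAsFactors = FALSE
  )
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  if (n > 0) {
    if (any(!df$kind %in% kinds_ok))
      stop("`kind` must be one of: ", paste(kinds_ok, collapse = ", "))
    if (any(df$time < 0)) stop("event times must be non-negative")
    if (is.unsorted(df$time)) stop("event times must be sorted")
    if (any(df$duration < 0)) stop("durations must be non-negative")
  }
  class(df) <- c("event_table", "data.frame")
  df
}

#' Row-bind event tables and re-sort by time
#' @param ... `event_table` objects.
#' @return a single sorted `event_table`.
#' @export
bind_events <- function(...) {
  parts <- Filter(function(x) nrow(x) > 0, list(...))
  if (length(parts) == 0) return(event_table())
  all_cols <- unique(unlist(lapply(parts, names)))
  parts <- lapply(parts, function(p) {
    for (nm in setdiff(all_cols, names(p))) p[[nm]] <- NA
    p[, all_cols, drop = FALSE]
  })
  out <- do.call(rbind, lapply(parts, as.data.frame))
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("event_table", "data.frame")
  out
}

#' Decoded 2-D hypothetical cursor trajectory
#'
#' @param x,y decoded cursor positions per bin.
#' @param vx,vy decoded velocities per bin.
#' @param bin_width bin width in seconds.
#' @param start_time time of the first bin, seconds.
#' @return An object of class `trajectory_series`.
#' @export
trajectory_series <- function(x, y, vx = NULL, vy = NULL, bin_width = 0.02,
                              start_time = 0) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n > 0 && (!all(is.finite(x)) || !all(is.finite(y))))
    stop("trajectory positions must be finite")
  structure(
    list(x = as.numeric(x), y = as.numeric(y),
         vx = if (is.null(vx)) rep(NA_real_, n) else as.numeric(vx),
         vy = if (is.null(vy)) rep(NA_real_, n) else as.numeric(vy),
         bin_width = bin_width, start_time = start_time),
    class = "trajectory_series"
  )
}

#' @export
print.trajectory_series <- function(x, ...) {
  cat(sprintf("<trajectory_series> %d bins of %g s, t0 = %g s\n",
              length(x$x), x$bin_width, x$start_time))
  invisible(x)
}

#' Extract a time window from a trajectory
#' @param traj a `trajectory_series`.
#' @param from,to window limits in seconds (`from` inclusive, `to` exclusive).
#' @return a `trajectory_series`.
#' @export
traj_window <- function(traj, from, to) {
  tt <- traj$start_time + (seq_along(traj$x) - 1L) * traj$bin_width
  keep <- tt >= from - 1e-9 & tt < to - 1e-9
  if (!any(keep)) stop("requested window contains no bins")
  trajectory_series(traj$x[keep], traj$y[keep], traj$vx[keep], traj$vy[keep],
                    traj$bin_width, start_time = tt[which(keep)[1L]])
}
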