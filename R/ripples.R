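#' Sliding-window z-scored ripple-band power
#'
#' Band power of the LFP within the broad ripple band (40-125 Hz,
#' fourth-order zero-phase Butterworth), smoothed over 20 ms and z-scored
#' against a centered 60 s sliding window.
#'
#' @param lfp numeric LFP series.
#' @param rate sampling rate, Hz (>= 250).
#' @param zscore_window z-scoring window, seconds (default 60).
#' @return numeric series of z-scored band power, same length as `lfp`.
#' @export
ripple_band_power <- function(lfp, rate, zscore_window = 60) {
  if (rate < 250) stop("rate must be >= 250 Hz for the 40-125 Hz band")
  if (length(lfp) < zscore_window * rate)
    stop("recording shorter than the z-scoring window")
  bf <- signal::butter(4, c(40, min(125, 0.45 * rate)) / (rate / 2), "pass")
  p <- signal::filtfilt(bf, lfp)^2
  p <- roll_mean_center(p, max(1L, round(0.02 * rate)))
  w <- round(zscore_window * rate)
  mu <- roll_mean_center(p, w)
  m2 <- roll_mean_center(p^2, w)
  sdv <- sqrt(pmax(0, m2 - mu^2))
  ifelse(sdv > 0, (p - mu) / sdv, 0)
}

# centered rolling mean with shrinking edges
roll_mean_center <- function(x, w) {
  out <- data.table::frollmean(x, w, align = "center")
  # fill edge NAs with the nearest valid value
  first_ok <- which(!is.na(out))[1]
  last_ok <- max(which(!is.na(out)))
  out[seq_len(first_ok - 1L)] <- out[first_ok]
  if (last_ok < length(out)) out[(last_ok + 1L):length(out)] <- out[last_ok]
  out
}

# local maxima of x with prominence > prom (prominence approximated as
# height above the larger of the minima separating the peak from its
# higher neighbors on each side)
find_peaks_prom <- function(x, prom) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  keep <- vapply(cand, function(i) {
    l <- i; while (l > 1 && x[l - 1] <= x[i]) l <- l - 1L
    r <- i; while (r < n && x[r + 1] <= x[i]) r <- r + 1L
    left_min <- min(x[l:i]); right_min <- min(x[i:r])
    base <- max(left_min, right_min)
    if (l == 1 && r == n) base <- min(left_min, right_min)
    (x[i] - base) > prom
  }, TRUE)
  cand[keep]
}

#' Detect cortical ripples on one LFP channel
#'
#' The signal is downsampled to 1000 Hz, band-pass filtered 60-100 Hz
#' (zero-phase fourth-order Butterworth), and the RMS over a 20 ms moving
#' average computed. Supra-90th-percentile segments are extracted; gaps
#' under 40 ms between neighboring segments are bridged; candidates of at
#' least 40 ms are kept. A candidate is confirmed iff the 120 Hz-lowpassed
#' LFP contains at least three distinct peaks (local maxima with
#' prominence above 10% of the candidate's peak-to-trough range) inside a
#' 40 ms window whose first and last peaks are not both within 7 ms of the
#' window's edges - equivalently, some consecutive peak triple spans at
#' most 33 ms.
#'
#' @param lfp numeric LFP series.
#' @param rate sampling rate, Hz (a multiple of 1000 or exactly 1000).
#' @param percentile RMS threshold percentile (default 0.90), taken over
#'   the full series.
#' @param start_time series start, seconds.
#' @return data.frame of confirmed ripple intervals (`start`, `end`,
#'   seconds).
#' @export
detect_ripples <- function(lfp, rate, percentile = 0.90, start_time = 0) {
  if (length(lfp) / rate < 10)
    stop("need >= 10 s of signal for percentile estimation")
  if (rate != 1000) {
    if (rate %% 1000 != 0)
      stop("rate must be 1000 Hz or an integer multiple")
    lfp <- signal::decimate(lfp, rate / 1000)
    rate <- 1000
  }
  bf <- signal::butter(4, c(60, 100) / (rate / 2), "pass")
  bp <- signal::filtfilt(bf, lfp)
  rms <- sqrt(roll_mean_center(bp^2, round(0.02 * rate)))
  thr <- stats::quantile(rms, percentile, names = FALSE)
  above <- rms > thr
  if (!any(above)) return(data.frame(start = numeric(0), end = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  seg <- data.frame(s = starts[r$values], e = ends[r$values])
  # bridge gaps < 40 ms
  gap_max <- round(0.04 * rate)
  if (nrow(seg) > 1) {
    merged <- seg[1, , drop = FALSE]
    for (i in 2:nrow(seg)) {
      if (seg$s[i] - merged$e[nrow(merged)] - 1L < gap_max)
        merged$e[nrow(merged)] <- seg$e[i]
      else merged <- rbind(merged, seg[i, ])
    }
    seg <- merged
  }
  seg <- seg[(seg$e - seg$s + 1L) >= round(0.04 * rate), , drop = FALSE]
  if (nrow(seg) == 0) return(data.frame(start = numeric(0),
                                        end = numeric(0)))
  lpf <- signal::butter(4, 120 / (rate / 2), "low")
  low <- signal::filtfilt(lpf, lfp)
  ok <- vapply(seq_len(nrow(seg)), function(i) {
    idx <- seg$s[i]:seg$e[i]
    x <- low[idx]
    pk <- find_peaks_prom(x, 0.1 * (max(x) - min(x)))
    if (length(pk) < 3) return(FALSE)
    spans <- (pk[-(1:2)] - pk[seq_len(length(pk) - 2L)]) / rate
    any(spans <= 0.033 + 1e-9)
  }, TRUE)
  seg <- seg[ok, , drop = FALSE]
  data.frame(start = start_time + (seg$s - 1L) / rate,
             end = start_time + seg$e / rate)
}

#' Detect ripples across channels and build the simultaneity count series
#'
#' Runs [detect_ripples()] per channel and counts, on a 1 ms grid, how many
#' channels are simultaneously inside a confirmed ripple.
#'
#' @param lfp an `lfp_recording` (see [simulate_lfp()]) or a channels x
#'   samples matrix.
#' @param rate sampling rate (taken from the recording if available).
#' @param start_time series start, seconds.
#' @param percentile RMS threshold percentile.
#' @return a list of class `ripple_table`: `intervals` (list per channel),
#'   `channel_count` (integer series at 1 ms), `step` (0.001),
#'   `start_time`, `magnitude_thresholds`.
#' @export
ripple_table <- function(lfp, rate = NULL, start_time = NULL,
                         percentile = 0.90) {
  if (inherits(lfp, "lfp_recording")) {
    vals <- lfp$values; rate <- lfp$rate; start_time <- lfp$start_time
  } else {
    vals <- lfp
    if (is.null(rate)) stop("rate required for a plain matrix")
    if (is.null(start_time)) start_time <- 0
  }
  n_ms <- ceiling(ncol(vals) / rate * 1000)
  counts <- integer(n_ms)
  ints <- vector("list", nrow(vals))
  for (c in seq_len(nrow(vals))) {
    iv <- detect_ripples(vals[c, ], rate, percentile, start_time)
    ints[[c]] <- iv
    if (nrow(iv) > 0) {
      for (k in seq_len(nrow(iv))) {
        a <- max(1L, round((iv$start[k] - start_time) * 1000) + 1L)
        b <- min(n_ms, round((iv$end[k] - start_time) * 1000))
        if (b >= a) counts[a:b] <- counts[a:b] + 1L
      }
    }
  }
  structure(list(intervals = ints, channel_count = counts, step = 0.001,
                 start_time = start_time,
                 magnitude_thresholds = c(1, 2, 4, 8, 16)),
            class = "ripple_table")
}

#' Proportion of STCEs inside ripple epochs across time offsets
#'
#' The timestamps of all STCEs are shifted by each offset (default -7 to
#' +7 s in 20 ms steps) and the proportion falling inside a ripple epoch
#' (channel count >= threshold) recomputed, per magnitude threshold. The
#' baseline is the fraction of the whole series inside ripple at that
#' threshold.
#'
#' @param stce_times STCE onset times, seconds.
#' @param rip a `ripple_table`.
#' @param offsets offset grid, seconds.
#' @param thresholds channel-count magnitude thresholds.
#' @return data.frame: `threshold`, `offset`, `proportion`, `baseline`.
#' @export
stce_ripple_alignment <- function(stce_times, rip,
                                  offsets = seq(-7, 7, by = 0.02),
                                  thresholds = c(1, 2, 4, 8, 16)) {
  n <- length(rip$channel_count)
  rows <- lapply(thresholds, function(th) {
    inrip <- rip$channel_count >= th
    base <- mean(inrip)
    prop <- vapply(offsets, function(o) {
      idx <- round((stce_times + o - rip$start_time) / rip$step) + 1L
      idx <- idx[idx >= 1L & idx <= n]
      if (length(idx) == 0) return(NA_real_)
      mean(inrip[idx])
    }, 0)
    data.frame(threshold = th, offset = offsets, proportion = prop,
               baseline = base)
  })
  do.call(rbind, rows)
}

#' Cross-correlogram between the template-matching signal and ripple counts
#'
#' Around each STCE, within a +/- `window` s span, the lagged correlation
#' between each dimension's template-matching (sliding correlation) signal
#' and the simultaneous-ripple channel count is computed on the 20 ms bin
#' grid; the per-event peak lag of the summed X+Y correlogram and the
#' median peak lag across events are reported. Events whose window is
#' truncated by a recording edge are skipped with a warning; zero-variance
#' count windows yield correlation 0 and no peak.
#'
#' @param corr a `correlation_series` covering the events.
#' @param rip a `ripple_table` on the same clock.
#' @param stce_times STCE onsets, seconds.
#' @param window half-window, seconds (default 5).
#' @return a list: `peak_lags` (per retained event), `median_peak_lag`,
#'   `lags`, `mean_ccx`, `mean_ccy`, `n_events`, `n_skipped`.
#' @export
stce_ripple_crosscorr <- function(corr, rip, stce_times, window = 5) {
  bw <- corr$bin_width
  lags <- seq(-window, window, by = bw)
  nl <- length(lags)
  wb <- round(window / bw)
  # ripple channel count resampled onto the correlation bin grid
  n_bins <- length(corr$cc_x)
  bt <- corr$start_time + (seq_len(n_bins) - 1L) * bw
  idx_ms <- round((bt - rip$start_time) / rip$step) + 1L
  cnt <- rep(NA_real_, n_bins)
  ok <- idx_ms >= 1L & idx_ms <= length(rip$channel_count)
  cnt[ok] <- rip$channel_count[idx_ms[ok]]
  ccx_all <- matrix(NA_real_, nl, 0)
  ccy_all <- matrix(NA_real_, nl, 0)
  peak_lags <- numeric(0)
  n_skip <- 0L
  for (t0 in stce_times) {
    b0 <- round((t0 - corr$start_time) / bw) + 1L
    if (b0 - wb < 1L || b0 + wb + wb > n_bins || b0 - wb - wb < 1L) {
      n_skip <- n_skip + 1L
      next
    }
    ev <- (b0 - wb):(b0 + wb)
    lag_cor <- function(sig) {
      vapply(seq_len(nl) - wb - 1L, function(kk) {
        a <- sig[ev]
        b <- cnt[ev + kk]
        if (any(is.na(b)) || stats::sd(b) == 0 || stats::sd(a) == 0)
          return(0)
        stats::cor(a, b)
      }, 0)
    }
    cx <- lag_cor(corr$cc_x)
    cy <- lag_cor(corr$cc_y)
    ccx_all <- cbind(ccx_all, cx)
    ccy_all <- cbind(ccy_all, cy)
    s <- cx + cy
    if (all(s == 0)) peak_lags <- c(peak_lags, NA_real_)
    else peak_lags <- c(peak_lags, lags[which.max(s)])
  }
  if (n_skip > 0)
    warning(sprintf("%d events skipped: window truncated by recording edge",
                    n_skip))
  list(peak_lags = peak_lags,
       median_peak_lag = stats::median(peak_lags, na.rm = TRUE),
       lags = lags,
       mean_ccx = if (ncol(ccx_all) > 0) rowMeans(ccx_all) else rep(NA, nl),
       mean_ccy = if (ncol(ccy_all) > 0) rowMeans(ccy_all) else rep(NA, nl),
       n_events = length(peak_lags), n_skipped = n_skip)
}
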