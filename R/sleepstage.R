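#' Short-time EEG power spectrogram
#'
#' Hann-windowed short-time power spectra (default 30 s windows, 50%
#' overlap), restricted to the 0.5-50 Hz analysis band and normalized to
#' unit total power per step. All-zero steps are flagged (`zero_step`)
#' rather than raising.
#'
#' @param eeg a preprocessed [eeg_recording()].
#' @param window window length, seconds (default 30).
#' @param overlap fractional overlap (default 0.5).
#' @return a list of class `eeg_spectrogram`: `times` (step centers,
#'   seconds), `freqs` (Hz), `power` (freqs x steps, unit column sums),
#'   `zero_step`, `params`.
#' @export
eeg_spectrogram <- function(eeg, window = 30, overlap = 0.5) {
  stopifnot(inherits(eeg, "eeg_recording"))
  fs <- eeg$rate
  wlen <- round(window * fs)
  if (length(eeg$samples) < wlen)
    stop("recording shorter than one spectrogram window")
  hop <- max(1L, round(wlen * (1 - overlap)))
  starts <- seq(1L, length(eeg$samples) - wlen + 1L, by = hop)
  han <- 0.5 - 0.5 * cos(2 * pi * seq(0, wlen - 1) / (wlen - 1))
  freqs_all <- (seq_len(wlen %/% 2 + 1L) - 1L) * fs / wlen
  keep <- freqs_all >= 0.5 & freqs_all <= 50
  P <- vapply(starts, function(s) {
    seg <- eeg$samples[s:(s + wlen - 1L)] * han
    sp <- abs(stats::fft(seg)[seq_len(wlen %/% 2 + 1L)])^2
    sp[keep]
  }, numeric(sum(keep)))
  P <- matrix(P, nrow = sum(keep))
  tot <- colSums(P)
  zero <- tot <= 0
  P[, !zero] <- sweep(P[, !zero, drop = FALSE], 2, tot[!zero], "/")
  structure(
    list(times = eeg$start_time + (starts - 1L + wlen / 2) / fs,
         freqs = freqs_all[keep], power = P, zero_step = zero,
         params = list(window = window, overlap = overlap, rate = fs)),
    class = "eeg_spectrogram")
}

#' 95% frequency power limit (FPL) per spectrogram step
#'
#' Per step, the normalized spectrum is cumulatively summed over frequency
#' and the first frequency at which the cumulative sum exceeds 0.95 is the
#' FPL. Flagged all-zero steps yield `NA`.
#'
#' @param spec an `eeg_spectrogram`.
#' @param limit cumulative-power threshold (default 0.95).
#' @return numeric vector of FPL values (Hz) per step.
#' @export
fpl_series <- function(spec, limit = 0.95) {
  stopifnot(inherits(spec, "eeg_spectrogram"))
  out <- vapply(seq_len(ncol(spec$power)), function(j) {
    if (spec$zero_step[j]) return(NA_real_)
    cs <- cumsum(spec$power[, j])
    spec$freqs[which(cs > limit)[1]]
  }, 0)
  out
}

#' Classify spectrogram steps as slow-wave sleep by FPL threshold
#'
#' @param fpl FPL per step (Hz).
#' @param threshold FPL cutoff in Hz; a step is SWS iff `fpl < threshold`.
#' @return logical vector (`NA` where FPL is `NA`).
#' @export
classify_sws <- function(fpl, threshold) {
  fpl < threshold
}

#' Compute the full sleep-stage series over a threshold grid
#'
#' @param eeg a preprocessed [eeg_recording()].
#' @param thresholds FPL thresholds in Hz (default `seq(2, 6, by = 0.5)`).
#' @param window,overlap spectrogram parameters.
#' @return a list of class `sleep_stage_series`: `times`, `fpl`,
#'   `thresholds`, `sws_labels` (steps x thresholds logical matrix),
#'   `spectrogram_params`.
#' @export
sleep_stage_series <- function(eeg, thresholds = seq(2, 6, by = 0.5),
                               window = 30, overlap = 0.5) {
  spec <- eeg_spectrogram(eeg, window, overlap)
  fpl <- fpl_series(spec)
  labs <- vapply(thresholds, function(th) classify_sws(fpl, th),
                 logical(length(fpl)))
  structure(
    list(times = spec$times, fpl = fpl, thresholds = thresholds,
         sws_labels = matrix(labs, ncol = length(thresholds)),
         spectrogram_params = spec$params),
    class = "sleep_stage_series")
}

#' STCE enrichment in slow-wave sleep
#'
#' Per FPL threshold: the fraction of the night classified SWS, the
#' fraction of STCEs falling in SWS steps (each STCE is assigned to the
#' spectrogram step containing its timestamp), a binomial 95% CI for the
#' proportional null (STCEs land in SWS proportionally to time spent
#' there), and a per-threshold binomial test. Across the grid, a
#' two-sample Kolmogorov-Smirnov test compares the observed-proportion and
#' expected-proportion curves.
#'
#' @param stces [event_table()] of STCEs (kind `"stce"`).
#' @param stages a `sleep_stage_series` covering the events.
#' @return a list of class `sws_enrichment`: `table` (per-threshold rows),
#'   `ks_p`, `n_stce`, `undefined` (TRUE with zero events).
#' @export
sws_enrichment <- function(stces, stages) {
  stopifnot(inherits(stages, "sleep_stage_series"))
  if (length(stages$thresholds) == 0) stop("empty threshold grid")
  times <- stces$time[stces$kind == "stce"]
  n_ev <- length(times)
  half <- stages$spectrogram_params$window / 2
  step_of <- function(t0) {
    j <- which(abs(stages$times - t0) <= half + 1e-9)
    if (length(j) == 0) NA_integer_ else
      j[which.min(abs(stages$times[j] - t0))]
  }
  steps <- vapply(times, step_of, 0L)
  steps <- steps[!is.na(steps)]
  rows <- lapply(seq_along(stages$thresholds), function(k) {
    lab <- stages$sws_labels[, k]
    frac_night <- mean(lab, na.rm = TRUE)
    if (n_ev == 0)
      return(data.frame(threshold = stages$thresholds[k],
                        frac_night_sws = frac_night, frac_stce_sws = NA,
                        ci_lo = NA, ci_hi = NA, binom_p = NA))
    in_sws <- lab[steps]
    obs <- mean(in_sws, na.rm = TRUE)
    n_used <- sum(!is.na(in_sws))
    ci <- stats::qbinom(c(0.025, 0.975), n_used, frac_night) / n_used
    bp <- stats::binom.test(sum(in_sws, na.rm = TRUE), n_used,
                            frac_night)$p.value
    data.frame(threshold = stages$thresholds[k], frac_night_sws = frac_night,
               frac_stce_sws = obs, ci_lo = ci[1], ci_hi = ci[2],
               binom_p = bp)
  })
  tab <- do.call(rbind, rows)
  ks_p <- if (n_ev > 0)
    suppressWarnings(stats::ks.test(tab$frac_stce_sws,
                                    tab$frac_night_sws)$p.value)
  else NA_real_
  structure(list(table = tab, ks_p = ks_p, n_stce = n_ev,
                 undefined = n_ev == 0),
            class = "sws_enrichment")
}
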