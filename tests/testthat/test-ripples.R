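# slow background the 120 Hz-lowpass peak rule should reject
make_bg_lfp <- function(n, rate = 1000, seed = 41, sd = 10) {
  set.seed(seed)
  signal::filtfilt(signal::butter(4, 30 / (rate / 2), "low"),
                   rnorm(n, 0, sd))
}

test_that("ripple-band power is z-scored and detects bursts", {
  rate <- 1000
  set.seed(42)
  x <- rnorm(rate * 90)
  z <- ripple_band_power(x, rate)
  expect_equal(mean(z), 0, tolerance = 0.05)
  expect_equal(sd(z), 1, tolerance = 0.15)
  # 80 Hz burst on a quiet background produces a local z peak > 3
  bg <- make_bg_lfp(rate * 90)
  tt <- seq(0, 0.1, by = 1 / rate)
  idx <- 45000 + seq_along(tt)
  bg[idx] <- bg[idx] + 5 * sd(bg) * sin(2 * pi * 80 * tt)
  zb <- ripple_band_power(bg, rate)
  expect_gt(max(zb[idx]), 3)
  # a pure 10 Hz signal carries almost no ripple-band power
  slow <- sin(2 * pi * 10 * seq(0, 90, by = 1 / rate))
  bp <- signal::filtfilt(signal::butter(4, c(40, 125) / 500, "pass"), slow)
  expect_lt(max(abs(bp[1000:80000])), 1e-3)
  expect_error(ripple_band_power(rnorm(100), rate), "shorter")
})

test_that("ripple detector accepts 80 Hz bursts and rejects slow bursts", {
  rate <- 1000
  bg <- make_bg_lfp(30 * rate)
  tt <- seq(0, 0.1, by = 1 / rate)
  x1 <- bg
  idx <- 15000 + seq_along(tt)
  x1[idx] <- x1[idx] + 5 * sd(bg) * sin(2 * pi * 80 * tt)
  r1 <- detect_ripples(x1, rate)
  expect_equal(nrow(r1), 1)
  expect_lt(abs(r1$start - 15.0), 0.2)    # covers the burst
  expect_gt(r1$end, 15.08)
  # 30 Hz burst of equal amplitude: peak criterion fails
  tt2 <- seq(0, 0.05, by = 1 / rate)
  x2 <- bg
  idx2 <- 15000 + seq_along(tt2)
  x2[idx2] <- x2[idx2] + 5 * sd(bg) * sin(2 * pi * 30 * tt2)
  expect_equal(nrow(detect_ripples(x2, rate)), 0)
  # determinism
  expect_identical(detect_ripples(x1, rate), detect_ripples(x1, rate))
})

test_that("nearby supra-threshold segments merge into one candidate", {
  rate <- 1000
  bg <- make_bg_lfp(30 * rate, seed = 43)
  amp <- 5 * sd(bg)
  t1 <- seq(0, 0.03, by = 1 / rate)       # 30 ms burst
  x <- bg
  x[15000 + seq_along(t1)] <- x[15000 + seq_along(t1)] +
    amp * sin(2 * pi * 80 * t1)
  gap <- 20                               # 20 ms silent gap
  x[15000 + length(t1) + gap + seq_along(t1)] <-
    x[15000 + length(t1) + gap + seq_along(t1)] + amp * sin(2 * pi * 80 * t1)
  r <- detect_ripples(x, rate)
  expect_equal(nrow(r), 1)
  expect_gte(r$end - r$start, 0.08)       # merged candidate spans both
})

test_that("detection is invariant to simulation at a higher rate", {
  rate_hi <- 4000
  n_s <- 30
  set.seed(44)
  bg_hi <- signal::filtfilt(signal::butter(4, 30 / (rate_hi / 2), "low"),
                            rnorm(n_s * rate_hi, 0, 10))
  tt <- seq(0, 0.1, by = 1 / rate_hi)
  idx <- 15 * rate_hi + seq_along(tt)
  bg_hi[idx] <- bg_hi[idx] + 5 * sd(bg_hi) * sin(2 * pi * 80 * tt)
  r_hi <- detect_ripples(bg_hi, rate_hi)
  r_lo <- detect_ripples(bg_hi[seq(1, length(bg_hi), by = 4)], 1000)
  expect_equal(nrow(r_hi), 1)
  expect_equal(nrow(r_lo), 1)
  expect_lt(abs(r_hi$start - r_lo$start), 0.02)
  expect_lt(abs(r_hi$end - r_lo$end), 0.02)
})

test_that("ripple fraction of the night shrinks with the channel threshold", {
  fx <- small_analysis()
  lfp <- simulate_lfp(fx$session$truth$injected_events, fx$cfg,
                      sleep_start = 641, sleep_end = 941)
  rt <- ripple_table(lfp)
  fracs <- vapply(c(1, 2, 4, 8), function(th)
    mean(rt$channel_count >= th), 0)
  expect_true(all(diff(fracs) <= 0))
})

test_that("STCE-ripple alignment peaks where events precede ripples", {
  # ripples everywhere: proportion 1 at every offset
  rt_full <- structure(list(intervals = list(), step = 0.001,
                            channel_count = rep(5L, 60000), start_time = 0,
                            magnitude_thresholds = c(1, 2, 4)),
                       class = "ripple_table")
  al <- stce_ripple_alignment(c(10, 20, 30), rt_full,
                              offsets = seq(-2, 2, by = 0.5),
                              thresholds = c(1, 4))
  expect_true(all(al$proportion == 1))
  expect_true(all(al$baseline == 1))
  # no ripples: proportion 0 everywhere
  rt_none <- rt_full; rt_none$channel_count <- rep(0L, 60000)
  al0 <- stce_ripple_alignment(c(10, 20, 30), rt_none,
                               offsets = seq(-2, 2, by = 0.5),
                               thresholds = 1)
  expect_true(all(al0$proportion == 0))
  # STCEs placed half a template (2 s) before 200 ms ripple epochs:
  # the curve peaks at offset ~ +2 s
  counts <- integer(60000)
  rip_at <- c(12, 22, 32, 42)
  for (t0 in rip_at) counts[(t0 * 1000):(t0 * 1000 + 200)] <- 3L
  rt <- rt_full; rt$channel_count <- counts
  al2 <- stce_ripple_alignment(rip_at - 2, rt,
                               offsets = seq(-7, 7, by = 0.02),
                               thresholds = 1)
  peak_off <- al2$offset[which.max(al2$proportion)]
  expect_lt(abs(peak_off - 2), 0.05)
})

test_that("STCE-ripple cross-correlograms recover a planted lag", {
  set.seed(45)
  bw <- 0.02
  n <- 6000                               # 120 s of correlation signal
  sig <- as.numeric(stats::filter(rnorm(n), 0.9, method = "recursive"))
  sig <- (sig - mean(sig)) / sd(sig)
  lag_s <- 2.2
  lag_bins <- round(lag_s / bw)
  cnt_bins <- c(rep(0, lag_bins), sig[seq_len(n - lag_bins)])
  corr <- structure(list(cc_x = sig, cc_y = sig, L = 100, bin_width = bw,
                         start_time = 0), class = "correlation_series")
  # expand counts onto a 1 ms grid
  counts_ms <- rep(cnt_bins, each = 20)
  rt <- structure(list(intervals = list(), channel_count = counts_ms,
                       step = 0.001, start_time = 0,
                       magnitude_thresholds = 1),
                  class = "ripple_table")
  ev <- c(30, 50, 70, 90)
  xc <- stce_ripple_crosscorr(corr, rt, ev, window = 5)
  expect_equal(xc$n_events, 4)
  expect_lt(abs(xc$median_peak_lag - 2.2), 0.05)
  # truncated event windows are skipped with a warning
  expect_warning(stce_ripple_crosscorr(corr, rt, c(3, 50), window = 5),
                 "skipped")
  # zero-variance counts: correlations 0, no peak reported
  rt0 <- rt; rt0$channel_count <- rep(2, length(counts_ms))
  xc0 <- stce_ripple_crosscorr(corr, rt0, 50, window = 5)
  expect_true(is.na(xc0$peak_lags[1]))
  expect_true(all(xc0$mean_ccx == 0))
})
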