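test_that("the Mann-Whitney p floor matches exact enumeration", {
  expect_equal(min_attainable_p(1, 100), 2 / 101, tolerance = 1e-12)
  expect_equal(min_attainable_p(1, 1), 1)
  expect_equal(min_attainable_p(1, 19), 0.1)
  # oracle: exact wilcox.test with the extreme ranking
  p_oracle <- wilcox.test(200, 1:100, exact = TRUE)$p.value
  expect_equal(min_attainable_p(1, 100), p_oracle, tolerance = 1e-12)
  p_oracle2 <- wilcox.test(c(8.5, 9.5), 1:7, exact = TRUE)$p.value
  expect_equal(min_attainable_p(2, 7), p_oracle2, tolerance = 1e-12)
  expect_error(min_attainable_p(0, 5), ">= 1")
})

test_that("phase randomization preserves per-segment spectra and means", {
  set.seed(22)
  tr <- make_bg_traj(4000, seed = 22)
  seg_s <- 10                             # 500-bin segments
  sur <- phase_randomize(tr, segment = seg_s, seed = 5)
  seg_bins <- 500
  for (s in c(1, 501, 3501)) {            # includes the final segment
    idx <- s:min(4000, s + seg_bins - 1)
    expect_equal(Mod(fft(sur$x[idx])), Mod(fft(tr$x[idx])),
                 tolerance = 1e-10)
    expect_equal(Mod(fft(sur$y[idx])), Mod(fft(tr$y[idx])),
                 tolerance = 1e-10)
    expect_equal(mean(sur$x[idx]), mean(tr$x[idx]), tolerance = 1e-10)
  }
  expect_true(all(is.finite(sur$x)))
  # applying the null twice stays within the same family: spectra unchanged
  sur2 <- phase_randomize(sur, segment = seg_s, seed = 6)
  idx <- 1:500
  expect_equal(Mod(fft(sur2$x[idx])), Mod(fft(tr$x[idx])), tolerance = 1e-10)
  expect_error(phase_randomize(trajectory_series(numeric(0), numeric(0))),
               "empty")
})

test_that("phase surrogates preserve the autocovariance of an AR process", {
  set.seed(23)
  n <- 8192
  ar <- as.numeric(stats::filter(rnorm(n), 0.9, method = "recursive"))
  tr <- trajectory_series(ar, ar, bin_width = 0.02)
  sur <- phase_randomize(tr, segment = n * 0.02, seed = 7)  # one segment
  acf_o <- acf(tr$x, lag.max = 5, plot = FALSE)$acf[-1]
  acf_s <- acf(sur$x, lag.max = 5, plot = FALSE)$acf[-1]
  expect_equal(acf_s, acf_o, tolerance = 0.05)
})

test_that("pseudo-template control reproduces the exact p floor", {
  set.seed(24)
  rest <- make_bg_traj(2000, seed = 31)
  ref <- make_bg_traj(3000, seed = 32)
  night <- make_bg_traj(5000, seed = 33)
  nd <- pseudo_template_control(rest, ref, night, template_bins = 100,
                                percentile = 98, n = 100, seed = 9,
                                observed = 10000)
  # observed exceeding every null count: smallest attainable p
  expect_true(all(nd$counts < 10000))
  expect_equal(nd$p_value, 0.019802, tolerance = 1e-6)
  # observed at the null median: clearly non-significant
  nd2 <- pseudo_template_control(rest, ref, night, template_bins = 100,
                                 percentile = 98, n = 50, seed = 9,
                                 observed = median(nd$counts))
  expect_gt(nd2$p_value, 0.5)
  # same seed reproduces the counts vector
  nd3 <- pseudo_template_control(rest, ref, night, template_bins = 100,
                                 percentile = 98, n = 50, seed = 9,
                                 observed = 1)
  nd4 <- pseudo_template_control(rest, ref, night, template_bins = 100,
                                 percentile = 98, n = 50, seed = 9,
                                 observed = 1)
  expect_identical(nd3$counts, nd4$counts)
  expect_error(pseudo_template_control(make_bg_traj(10, 1), ref, night,
                                       100, 98, 10, 1, 1), "shorter")
})

test_that("phase-randomized control flags planted structure, not noise", {
  # thresholds are calibrated, as in the full analysis, on a reference
  # epoch that itself contains template matches (task-like trials), so the
  # percentile lands in true-match range
  tmpl <- make_smooth_template(100)
  plant <- function(tr, sites, amp = 3) {
    for (s in sites) {
      idx <- s:(s + 99)
      tr$x[idx] <- tr$x[idx] + amp * sd(tr$x) * tmpl$x_template
      tr$y[idx] <- tr$y[idx] + amp * sd(tr$y) * tmpl$y_template
    }
    tr
  }
  ref <- plant(make_bg_traj(6000, seed = 42), seq(200, 5700, by = 280))
  night <- plant(make_bg_traj(12000, seed = 41),
                 seq(400, 11400, by = 1000))
  co_ref <- sliding_correlation(ref, tmpl)
  tx <- quantile(co_ref$cc_x, 0.98, names = FALSE)
  ty <- quantile(co_ref$cc_y, 0.98, names = FALSE)
  obs <- nrow(detect_stce(sliding_correlation(night, tmpl), tx, ty)$events)
  nd <- phase_randomized_control(night, tmpl, tx, ty, n = 60, seed = 10,
                                 observed = obs)
  expect_gt(obs, quantile(nd$counts, 0.95))
  expect_lt(nd$p_empirical, 0.05)
  # a structure-free trajectory is not significant
  bg <- make_bg_traj(12000, seed = 43)
  nd2 <- phase_randomized_control(bg, tmpl, tx, ty, n = 60, seed = 11)
  expect_gt(nd2$p_empirical, 0.05)
  # degenerate single-surrogate t test refused
  expect_error(phase_randomized_control(bg, tmpl, tx, ty, n = 1),
               "degenerate")
})

test_that("pseudo-template null counts carry no order dependence", {
  rest <- make_bg_traj(1500, seed = 51)
  ref <- make_bg_traj(1500, seed = 52)
  night <- make_bg_traj(1500, seed = 53)
  nd <- pseudo_template_control(rest, ref, night, 80, 98, n = 30, seed = 12,
                                observed = 1)
  # exchangeability smoke check: no trend of counts with iteration index
  ct <- cor.test(seq_along(nd$counts), nd$counts, method = "spearman",
                 exact = FALSE)
  expect_gt(ct$p.value, 0.01)
})
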