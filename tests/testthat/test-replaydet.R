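test_that("template averaging follows the two-sample formulas", {
  bw <- 0.02
  n <- 600
  base <- sin(seq(0, 4 * pi, length.out = 100))
  tr <- trajectory_series(rep(base, 6), rep(-base, 6), bin_width = bw)
  trials3 <- event_table(time = c(0, 2, 4), duration = 2, kind = "trial",
                         label = "target", success = TRUE)
  # identical trials: template equals any single trial (mean-centered)
  tm <- build_templates(tr, trials3)
  expect_equal(tm$x_template, base - mean(base), tolerance = 1e-12)
  expect_equal(tm$n_trials, 3)
  # one trial: template is that trial, SEM zero
  tm1 <- build_templates(tr, trials3[1, ])
  expect_equal(tm1$x_template, base - mean(base), tolerance = 1e-12)
  expect_true(all(tm1$sem_x == 0))
  # two distinct equal-length trials: pointwise mean, SEM = |diff| / 2 / sqrt(2)
  set.seed(11)
  a <- rnorm(100); b <- rnorm(100)
  tr2 <- trajectory_series(c(a, b), c(b, a), bin_width = bw)
  trials2 <- event_table(time = c(0, 2), duration = 2, kind = "trial",
                         label = "target", success = TRUE)
  tm2 <- build_templates(tr2, trials2)
  ac <- a - mean(a); bc <- b - mean(b)
  expect_equal(tm2$x_template, (ac + bc) / 2, tolerance = 1e-12)
  # sd of two values = |diff| / sqrt(2); SEM = sd / sqrt(2) = |diff| / 2
  expect_equal(tm2$sem_x, abs(ac - bc) / 2, tolerance = 1e-12)
  # no successful target trials: error
  bad <- event_table(time = 0, duration = 2, kind = "trial",
                     label = "target", success = FALSE)
  expect_error(build_templates(tr, bad), "successful")
})

test_that("sliding correlation equals the per-window Pearson oracle", {
  set.seed(12)
  x <- rnorm(60)
  tmpl <- make_smooth_template(10)
  tr <- trajectory_series(x, rev(x), bin_width = 0.02)
  co <- sliding_correlation(tr, tmpl)
  oracle_x <- vapply(1:51, function(t) cor(x[t:(t + 9)], tmpl$x_template), 0)
  expect_equal(co$cc_x, oracle_x, tolerance = 1e-10)
  expect_length(co$cc_x, 60 - 10 + 1)
  # exact and negated copies hit +1 / -1
  y <- c(rnorm(20), tmpl$x_template, rnorm(10), -tmpl$x_template, rnorm(5))
  co2 <- sliding_correlation(trajectory_series(y, y, bin_width = 0.02), tmpl)
  expect_equal(co2$cc_x[21], 1, tolerance = 1e-10)
  expect_equal(co2$cc_x[41], -1, tolerance = 1e-10)
  # flat (zero-variance) windows give 0, not NaN
  z <- c(rep(5, 30), rnorm(30))
  co3 <- sliding_correlation(trajectory_series(z, z, bin_width = 0.02), tmpl)
  expect_equal(co3$cc_x[1], 0)
  expect_true(all(is.finite(co3$cc_x)))
  expect_error(sliding_correlation(trajectory_series(rnorm(5), rnorm(5)),
                                   tmpl), "longer")
})

make_corr <- function(cx, cy, bw = 0.02, t0 = 0, L = 5) {
  structure(list(cc_x = cx, cc_y = cy, L = L, bin_width = bw,
                 start_time = t0), class = "correlation_series")
}

test_that("STCE detection applies the simultaneity and merging rules", {
  n <- 30
  cx <- rep(0.9, n)
  cy <- rep(-0.5, n)
  # x above, y below everywhere: no events
  expect_equal(nrow(detect_stce(make_corr(cx, cy), 0.5, 0.5)$events), 0)
  # both above only in bins 10-12: one event at bin 10
  cy2 <- rep(-0.5, n); cy2[10:12] <- 0.9
  det <- detect_stce(make_corr(cx, cy2), 0.5, 0.5)
  expect_equal(nrow(det$events), 1)
  expect_equal(det$events$time, (10 - 1) * 0.02)
  # gap at 11-13: two events
  cy3 <- rep(-0.5, n); cy3[c(10, 14)] <- 0.9
  det2 <- detect_stce(make_corr(cx, cy3), 0.5, 0.5)
  expect_equal(nrow(det2$events), 2)
  expect_equal(det2$events$time, c(9, 13) * 0.02)
})

test_that("detection agrees with exhaustive evaluation and shifts with time", {
  set.seed(13)
  n <- 200
  cx <- runif(n, -1, 1); cy <- runif(n, -1, 1)
  det <- detect_stce(make_corr(cx, cy), 0.2, 0.1)
  marked <- cx >= 0.2 & cy >= 0.1
  starts <- which(marked & !c(FALSE, marked[-n]))   # exhaustive oracle
  expect_equal(det$events$time, (starts - 1) * 0.02)
  # shift equivariance: shifting the series start shifts all events
  det_sh <- detect_stce(make_corr(cx, cy, t0 = 1.0), 0.2, 0.1)
  expect_equal(det_sh$events$time, det$events$time + 1.0)
})

test_that("Youden's J handles edge cases and rejects bad counts", {
  expect_equal(youden_j(10, 10, 0, 10), 1)
  expect_equal(youden_j(0, 10, 10, 10), -1)
  expect_error(youden_j(5, 0, 1, 10), "positive")
  expect_error(youden_j(11, 10, 0, 10), "hits")
})

test_that("threshold optimization maximizes J with ties to higher percentile", {
  fx <- small_analysis()
  sweep <- fx$thr$sweep
  # STCE count is non-increasing in the threshold percentile
  expect_true(all(diff(sweep$n_stce) <= 0))
  # reported optimum attains the sweep maximum, ties at higher percentile
  best_j <- max(sweep$youden_j)
  expect_equal(fx$thr$youden_j, best_j)
  expect_equal(fx$thr$percentile,
               max(sweep$percentile[sweep$youden_j == best_j]))
  expect_error(optimize_threshold(
    make_corr(runif(50), runif(50)),
    event_table(time = 1, duration = 1, kind = "sync", label = "x")),
    "trials")
})

test_that("template dilation is spline-exact and records tau", {
  tmpl <- make_smooth_template(20)
  expect_identical(dilate_template(tmpl, 1), tmpl)
  # linear ramp: splines reproduce it exactly at half the bins
  ramp <- tmpl
  ramp$x_template <- seq(0, 1, length.out = 20)
  ramp$y_template <- seq(1, 0, length.out = 20)
  d2 <- dilate_template(ramp, 2)
  expect_length(d2$x_template, 10)
  expect_equal(d2$x_template, seq(0, 1, length.out = 10), tolerance = 1e-10)
  expect_equal(d2$tau, 2)
  expect_equal(d2$duration, 10 * tmpl$bin_width)
  # tau = 10 on 20 bins leaves 2 bins; beyond that errors
  expect_length(dilate_template(tmpl, 10)$x_template, 2)
  expect_error(dilate_template(tmpl, 15), "fewer than 2")
  expect_error(dilate_template(tmpl, -1), "tau")
})

test_that("the default tau grid spans 0.1-10 with the analyzed speeds", {
  g <- default_tau_grid()
  expect_length(g, 18)
  expect_equal(min(g), 0.1)
  expect_equal(max(g), 10)
  expect_true(all(c(1, 2, 3, 4) %in% g))
})

test_that("compression sweep reduces to the base analysis at tau = 1", {
  fx <- small_analysis()
  sl <- fx$session$epochs[fx$session$epochs$name == "sleep", ]
  tsl <- traj_window(fx$traj, sl$start, sl$end)
  base <- detect_stce(sliding_correlation(tsl, fx$template),
                      fx$thr$threshold_x, fx$thr$threshold_y)
  sw <- compression_sweep(tsl, fx$template, 1,
                          fx$thr$threshold_x, fx$thr$threshold_y)
  expect_equal(sw$n_stce, nrow(base$events))
  # a trajectory shorter than every dilated template: zero counts
  tiny <- trajectory_series(rnorm(3), rnorm(3), bin_width = 0.02)
  sw0 <- compression_sweep(tiny, fx$template, c(0.5, 1),
                           fx$thr$threshold_x, fx$thr$threshold_y)
  expect_equal(sw0$n_stce, c(0L, 0L))
  expect_error(compression_sweep(tsl, fx$template, numeric(0), 0.9, 0.9),
               "non-empty")
})
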