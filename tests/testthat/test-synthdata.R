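test_that("session trial structure matches the task design", {
  cfg <- synth_config(n_channels = 8, calib_duration = 60,
                      rest_duration = 30, sleep_duration = 0,
                      replay_schedule = data.frame(time = numeric(0),
                                                   tau = numeric(0),
                                                   amplitude = numeric(0)),
                      seed = 1)
  s <- simulate_session(cfg)
  trials <- s$events[s$events$kind == "trial" &
                       s$events$label %in% c("target", "distractor"), ]
  expect_equal(nrow(trials), 160)
  expect_equal(sum(trials$label == "target"), 120)
  expect_equal(sum(trials$label == "distractor"), 40)
  # every distractor differs from the target sequence
  tgt <- paste(s$truth$target_sequence, collapse = "-")
  expect_true(all(trials$seq[trials$label == "distractor"] != tgt))
  expect_true(all(trials$seq[trials$label == "target"] == tgt))
})

test_that("empty replay schedule injects nothing", {
  cfg <- small_session_config()
  cfg$replay_schedule <- data.frame(time = numeric(0), tau = numeric(0),
                                    amplitude = numeric(0))
  cfg$n_channels <- 8
  cfg$sleep_duration <- 60
  s <- simulate_session(cfg)
  expect_equal(nrow(s$truth$injected_events), 0)
})

test_that("identical config and seed reproduce the session exactly", {
  cfg <- synth_config(n_channels = 8, calib_duration = 30,
                      rest_duration = 30, sleep_duration = 120,
                      n_blocks = 1, sws_cycle = c(sws = 60, nsws = 30),
                      replay_schedule = data.frame(time = 30, tau = 1,
                                                   amplitude = 2),
                      seed = 5)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a$features$values, b$features$values)
  expect_identical(a$events, b$events)
  expect_identical(a$eeg$samples, b$eeg$samples)
  expect_identical(a$truth$injected_events, b$truth$injected_events)
})

test_that("invalid configuration errors name the offending field", {
  expect_error(synth_config(bin_width = 0), "bin_width")
  expect_error(synth_config(n_channels = 0), "n_channels")
  expect_error(synth_config(target_per_block = 20), "target_per_block")
  expect_error(
    synth_config(replay_schedule = data.frame(time = 10, tau = -1,
                                              amplitude = 1)),
    "replay_schedule")
  expect_error(
    synth_config(sleep_duration = 100,
                 replay_schedule = data.frame(time = 200, tau = 1,
                                              amplitude = 1)),
    "replay_schedule")
})

test_that("cosine tuning drives the feature model as specified", {
  cfg <- synth_config(n_channels = 4, noise_sd = 0, seed = 1)
  set.seed(2)
  truth <- list(preferred = rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1)),
                depth_sbp = rep(1, 4), baseline_sbp = rep(2, 4),
                rate_bin = rep(1, 4), depth_tx = rep(0, 4))
  # depth 0 on tx, noise 0 on sbp, zero velocity: sbp constant at baseline
  v0 <- matrix(0, 2, 50)
  truth0 <- truth; truth0$depth_sbp <- rep(0, 4)
  fs0 <- simulate_tuned_features(v0, truth0, cfg)
  sbp_rows <- which(fs0$feature_meta$kind == "sbp")
  expect_true(all(fs0$values[sbp_rows, ] == 2))
  # velocity aligned with the preferred direction maximizes the response
  angles <- seq(0, 2 * pi, length.out = 33)[-33]
  resp <- vapply(angles, function(a) {
    fs <- simulate_tuned_features(matrix(c(cos(a), sin(a)), 2, 1), truth, cfg)
    fs$values[1, 1]                       # channel 1 sbp, preferred (1, 0)
  }, 0)
  expect_equal(angles[which.max(resp)], 0)
})

test_that("OLS on generated features recovers preferred directions", {
  cfg <- synth_config(n_channels = 6, noise_sd = 0.1, tuning_depth = 1,
                      seed = 1)
  set.seed(3)
  ang_true <- runif(6, 0, 2 * pi)
  truth <- list(preferred = cbind(cos(ang_true), sin(ang_true)),
                depth_sbp = rep(1, 6), baseline_sbp = rep(1, 6),
                rate_bin = rep(1, 6), depth_tx = rep(0.5, 6))
  n <- 10000
  theta <- runif(n, 0, 2 * pi)
  v <- rbind(cos(theta), sin(theta))
  fs <- simulate_tuned_features(v, truth, cfg)
  sbp <- fs$values[fs$feature_meta$kind == "sbp", ]
  X <- cbind(1, t(v))
  beta <- solve(crossprod(X), crossprod(X, t(sbp)))   # independent OLS oracle
  ang_hat <- atan2(beta[3, ], beta[2, ])
  err <- abs(((ang_hat - ang_true + pi) %% (2 * pi)) - pi) * 180 / pi
  expect_true(all(err < 5))
})

test_that("replay injection is additive, local, and scales with tau", {
  cfg <- synth_config(n_channels = 4, noise_sd = 1, seed = 1)
  set.seed(4)
  bg <- feature_series(matrix(rnorm(8 * 500), 8, 500), 0.02)
  pat <- matrix(rnorm(8 * 100), 8, 100)
  # amplitude 0: output identical to input
  r0 <- embed_replay(bg, pat, data.frame(time = 2, tau = 1, amplitude = 0))
  expect_equal(r0$features$values, bg$values)
  # tau = 2: footprint is half the pattern bin count
  r2 <- embed_replay(bg, pat, data.frame(time = 2, tau = 2, amplitude = 1))
  expect_equal(r2$events$duration, 50 * 0.02)
  # two disjoint injections: differences confined to the footprints
  rr <- embed_replay(bg, pat,
                     data.frame(time = c(1, 6), tau = c(1, 2),
                                amplitude = c(1, 2)))
  d <- rr$features$values - bg$values
  changed <- which(colSums(abs(d)) > 0)
  w1 <- 51:150                            # bins of [1, 3) s footprint
  w2 <- 301:350                           # bins of [6, 7) s footprint
  expect_true(all(changed %in% c(w1, w2)))
  expect_equal(d[, w1], pat, tolerance = 1e-12)
  # injection overlapping the segment end errors
  expect_error(embed_replay(bg, pat, data.frame(time = 9.5, tau = 1,
                                                amplitude = 1)),
               "overlaps")
})

test_that("EEG generator separates slow-wave and wake spectra", {
  cfg <- synth_config(n_channels = 8, seed = 1)
  set.seed(5)
  sws <- preprocess_eeg(simulate_eeg(
    data.frame(onset = 0, duration = 120, stage = "sws"), cfg,
    sync_taps = FALSE))
  sp <- eeg_spectrogram(sws, window = 30)
  delta_frac <- colSums(sp$power[sp$freqs < 4, , drop = FALSE])
  expect_true(all(delta_frac >= 0.8))     # Welch-style oracle on the spectrum
  wake <- preprocess_eeg(simulate_eeg(
    data.frame(onset = 0, duration = 120, stage = "wake"), cfg,
    sync_taps = FALSE))
  fpl <- fpl_series(eeg_spectrogram(wake, window = 30))
  expect_true(all(fpl > 6))
  empty <- simulate_eeg(data.frame(onset = numeric(0),
                                   duration = numeric(0),
                                   stage = character(0)), cfg)
  expect_equal(length(empty$samples), 0)
})

test_that("downstream detection recovers injected replay in a session", {
  fx <- small_analysis()
  sl <- fx$session$epochs[fx$session$epochs$name == "sleep", ]
  tsl <- traj_window(fx$traj, sl$start, sl$end)
  sw <- compression_sweep(tsl, fx$template, c(1, 2),
                          fx$thr$threshold_x, fx$thr$threshold_y)
  ev <- do.call(bind_events, attr(sw, "events"))
  inj <- fx$session$truth$injected_events
  hit <- vapply(seq_len(nrow(inj)), function(i)
    any(ev$time >= inj$time[i] - fx$template$duration &
          ev$time <= inj$time[i] + inj$duration[i]), TRUE)
  expect_gte(mean(hit), 0.8)
  # conservative false-positive load: no more than one spurious event in
  # the (3 min) rest epoch, consistent with <= 1 per rest hour
  rest <- fx$session$epochs[fx$session$epochs$name == "rest_pre", ]
  tr <- traj_window(fx$traj, rest$start, rest$end)
  det_rest <- detect_stce(sliding_correlation(tr, fx$template),
                          fx$thr$threshold_x, fx$thr$threshold_y)
  expect_lte(nrow(det_rest$events), 1)
})
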