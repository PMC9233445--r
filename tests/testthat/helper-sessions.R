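# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

# A compact session exercising every stage: 48 channels, short segments,
# six injected replay events alternating tau 1 and 2 at 3 SD.
small_session_config <- function(seed = 7) {
  synth_config(
    n_channels = 48, calib_duration = 120, rest_duration = 180,
    sleep_duration = 600, n_blocks = 2,
    sws_cycle = c(sws = 240, nsws = 120),
    replay_schedule = data.frame(time = seq(30, 500, length.out = 6),
                                 tau = rep(c(1, 2), 3), amplitude = 3),
    eeg_clock_offset = -3.2, n_lfp_channels = 8, seed = seed)
}

# session + decoder + trajectory + templates + thresholds, cached
small_analysis <- function() {
  if (!is.null(.fixtures$small)) return(.fixtures$small)
  cfg <- small_session_config()
  s <- simulate_session(cfg)
  cal <- s$epochs[s$epochs$name == "calibration", ]
  model <- calibrate(fs_window(s$features, cal$start, cal$end),
                     s$events[s$events$label == "calibration", ])
  traj <- decode(s$features, model)
  task <- s$epochs[s$epochs$name == "task", ]
  trials <- s$events[s$events$kind == "trial" &
                       s$events$label %in% c("target", "distractor"), ]
  traj_task <- traj_window(traj, task$start, task$end)
  template <- build_templates(traj_task, trials)
  thr <- optimize_threshold(sliding_correlation(traj_task, template), trials)
  .fixtures$small <- list(cfg = cfg, session = s, model = model, traj = traj,
                          trials = trials, traj_task = traj_task,
                          template = template, thr = thr)
  .fixtures$small
}

# The desk-scale study session: full channel count and block structure,
# 1 h sleep with the default schedule of 20 injections (tau 1 and 2,
# amplitude 3 SD), shortened rests. Seed fixed once.
acceptance_config <- function() {
  synth_config(rest_duration = 600, sleep_duration = 3600, seed = 42)
}

acceptance_analysis <- function() {
  if (!is.null(.fixtures$acc)) return(.fixtures$acc)
  cfg <- acceptance_config()
  s <- simulate_session(cfg)
  cal <- s$epochs[s$epochs$name == "calibration", ]
  model <- calibrate(fs_window(s$features, cal$start, cal$end),
                     s$events[s$events$label == "calibration", ])
  traj <- decode(s$features, model)
  task <- s$epochs[s$epochs$name == "task", ]
  trials <- s$events[s$events$kind == "trial" &
                       s$events$label %in% c("target", "distractor"), ]
  traj_task <- traj_window(traj, task$start, task$end)
  template <- build_templates(traj_task, trials)
  thr <- optimize_threshold(sliding_correlation(traj_task, template), trials)
  sl <- s$epochs[s$epochs$name == "sleep", ]
  traj_sleep <- traj_window(traj, sl$start, sl$end)
  .fixtures$acc <- list(cfg = cfg, session = s, model = model, traj = traj,
                        trials = trials, traj_task = traj_task,
                        template = template, thr = thr,
                        traj_sleep = traj_sleep)
  .fixtures$acc
}

# Stationary background trajectory (leaky-integrated AR(1) velocity),
# the null process the decoder produces from tuning-free noise.
make_bg_traj <- function(n_bins, seed, bin_width = 0.02, start_time = 0) {
  set.seed(seed)
  v_x <- as.numeric(stats::filter(rnorm(n_bins), 0.8, method = "recursive"))
  v_y <- as.numeric(stats::filter(rnorm(n_bins), 0.8, method = "recursive"))
  trajectory_series(
    as.numeric(stats::filter(bin_width * v_x, 0.995, method = "recursive")),
    as.numeric(stats::filter(bin_width * v_y, 0.995, method = "recursive")),
    v_x, v_y, bin_width, start_time)
}

# fixed smooth template pair of L bins
make_smooth_template <- function(L = 100, bin_width = 0.02) {
  tt <- seq(0, 2 * pi, length.out = L)
  structure(list(x_template = sin(tt), y_template = cos(2 * tt),
                 sem_x = rep(0, L), sem_y = rep(0, L),
                 duration = L * bin_width, tau = 1, n_trials = 1,
                 bin_width = bin_width),
            class = "template_pair")
}
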