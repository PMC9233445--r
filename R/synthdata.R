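#' Configuration for a synthetic recording session
#'
#' Builds the configuration object consumed by [simulate_session()]. Defaults
#' reproduce the study conditions the analysis assumes: two 96-channel arrays
#' (192 channels, two features each), 20 ms bins, a 5 min center-out
#' calibration block with a stepwise error-attenuation schedule, 30 min rest
#' periods, 10 task blocks of 16 trials (12 target-sequence, 4 distractor,
#' 4-target sequences), 512 Hz single-channel EEG, and an overnight segment
#' with slow-wave / non-slow-wave alternation into which ground-truth replay
#' events are injected.
#'
#' @param n_channels number of recording channels (two arrays, medial first).
#' @param bin_width feature bin width in seconds.
#' @param tuning_depth cosine-tuning gain: feature deviation per unit speed,
#'   in background-noise SD units for spike-band power features.
#' @param lateral_gain multiplier on `tuning_depth` for lateral-array
#'   channels (lateral activity is sparser and less task-linked).
#' @param noise_sd spike-band power noise SD (feature units).
#' @param tx_rate_hz baseline threshold-crossing rate per channel, Hz.
#' @param calib_duration,rest_duration,sleep_duration segment durations, s.
#' @param n_blocks,trials_per_block,target_per_block task block structure.
#' @param sequence_length targets per trial.
#' @param demo_duration cue-demonstration time preceding each trial, s.
#' @param leg_duration movement time per target acquisition, s.
#' @param trial_gap gap between trials, s.
#' @param success_rate_target,success_rate_distractor per-trial success
#'   probabilities.
#' @param eeg_rate EEG sampling rate, Hz.
#' @param sws_cycle numeric `c(sws = , nsws = )` epoch durations in seconds
#'   for the alternating overnight sleep architecture.
#' @param replay_schedule data.frame with columns `time` (seconds after
#'   sleep onset), `tau` (temporal compression factor, > 0) and `amplitude`
#'   (injection gain, in background-SD units). `NULL` for the default
#'   schedule of 20 events alternating tau 1 and 2 at amplitude 3, placed in
#'   slow-wave epochs; use a 0-row data.frame for no injections.
#' @param ripple_coupling list with `prob` (probability that an injected
#'   replay event is accompanied by a ripple burst) and `lag` (seconds from
#'   injection onset to burst center, or `"mid"` for half the injected
#'   footprint).
#' @param ea_schedule error-attenuation values applied stepwise over the
#'   first 90 s of calibration. Affects only the simulated closed-loop
#'   cursor; offline analysis never consumes it.
#' @param eeg_clock_offset constant offset of the EEG device clock relative
#'   to the intracortical clock, seconds.
#' @param n_lfp_channels medial channels for which 1 kHz LFP is synthesized.
#' @param seed RNG seed.
#'
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_channels = 192,
                         bin_width = 0.02,
                         tuning_depth = 1.0,
                         lateral_gain = 0.1,
                         noise_sd = 1.0,
                         tx_rate_hz = 50,
                         calib_duration = 300,
                         rest_duration = 1800,
                         sleep_duration = 3600,
                         n_blocks = 10,
                         trials_per_block = 16,
                         target_per_block = 12,
                         sequence_length = 4,
                         demo_duration = 3,
                         leg_duration = 1,
                         trial_gap = 1,
                         success_rate_target = 0.908,
                         success_rate_distractor = 0.825,
                         eeg_rate = 512,
                         sws_cycle = c(sws = 1200, nsws = 600),
                         replay_schedule = NULL,
                         ripple_coupling = list(prob = 0.9, lag = "mid"),
                         ea_schedule = seq(0.9, 0, by = -0.1),
                         eeg_clock_offset = 0,
                         n_lfp_channels = 16,
                         seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  if (is.null(cfg$replay_schedule))
    cfg$replay_schedule <- default_replay_schedule(cfg)
  validate_config(cfg)
  cfg
}

default_replay_schedule <- function(cfg) {
  sws_starts <- sws_epochs(cfg)$start
  if (length(sws_starts) == 0 || cfg$sleep_duration <= 0)
    return(data.frame(time = numeric(0), tau = numeric(0),
                      amplitude = numeric(0)))
  ep <- sws_epochs(cfg)
  n_ev <- 20L
  per <- ceiling(n_ev / nrow(ep))
  times <- unlist(lapply(seq_len(nrow(ep)), function(i) {
    seq(ep$start[i] + 60, ep$end[i] - 60, length.out = per)
  }))[seq_len(n_ev)]
  times <- sort(times)
  data.frame(time = times, tau = rep(c(1, 2), length.out = n_ev),
             amplitude = 3)
}

# slow-wave epochs within the sleep segment, relative to sleep onset
sws_epochs <- function(cfg) {
  if (cfg$sleep_duration <= 0)
    return(data.frame(start = numeric(0), end = numeric(0)))
  cyc <- sum(cfg$sws_cycle)
  starts <- seq(0, cfg$sleep_duration - 1, by = cyc)
  ends <- pmin(starts + cfg$sws_cycle[["sws"]], cfg$sleep_duration)
  data.frame(start = starts, end = ends)[ends > starts, , drop = FALSE]
}

validate_config <- function(cfg) {
  chk <- function(ok, field, why)
    if (!ok) stop(sprintf("invalid config field `%s`: %s", field, why),
                  call. = FALSE)
  chk(cfg$bin_width > 0, "bin_width", "must be > 0")
  chk(cfg$n_channels >= 1, "n_channels", "must be >= 1")
  chk(cfg$target_per_block >= 0 &&
        cfg$target_per_block <= cfg$trials_per_block,
      "target_per_block", "must lie in [0, trials_per_block]")
  chk(cfg$eeg_rate > 0, "eeg_rate", "must be > 0")
  chk(all(cfg$replay_schedule$tau > 0), "replay_schedule",
      "tau must be > 0")
  chk(all(cfg$replay_schedule$time >= 0 &
            cfg$replay_schedule$time < pmax(cfg$sleep_duration, 0)),
      "replay_schedule", "times must lie inside the sleep segment")
  chk(cfg$noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(cfg$sequence_length >= 1, "sequence_length", "must be >= 1")
  invisible(cfg)
}

# Four task targets on the unit circle (corner layout) and the
# radial-eight calibration directions.
task_target_angles <- function() c(45, 135, 225, 315) * pi / 180
calib_angles <- function() seq(0, 315, by = 45) * pi / 180

#' Per-channel tuning ground truth
#'
#' Draws preferred directions, baselines, depths and baseline rates for every
#' channel. Medial channels (first half) carry the full tuning depth; lateral
#' channels are attenuated by `lateral_gain`.
#'
#' @param cfg a `synth_config`.
#' @return list with per-channel tuning parameters.
#' @keywords internal
make_tuning <- function(cfg) {
  nc <- cfg$n_channels
  half <- ceiling(nc / 2)
  ang <- stats::runif(nc, 0, 2 * pi)
  gain <- rep(c(1, cfg$lateral_gain), c(half, nc - half)) *
    stats::runif(nc, 0.6, 1.4)
  list(
    preferred = cbind(cos(ang), sin(ang)),
    depth_sbp = cfg$tuning_depth * gain,
    baseline_sbp = stats::runif(nc, 0.5, 1.5),
    rate_bin = cfg$tx_rate_hz * cfg$bin_width * stats::runif(nc, 0.6, 1.4),
    depth_tx = 0.8 * gain
  )
}

#' Simulate cosine-tuned neural features from an intended-velocity series
#'
#' Feature model per channel c and bin t with intended velocity `v_t`:
#' spike-band power = `baseline_c + depth_c * (d_c . v_t) + N(0, noise_sd)`;
#' threshold crossings ~ Poisson with rate
#' `rate_c * max(0, 1 + depth_tx_c * (d_c . v_t))`, where `d_c` is the
#' channel's preferred direction. This is the simplest generative model
#' consistent with calibration of a linear decoder.
#'
#' @param velocity 2 x n numeric matrix of intended velocity per bin.
#' @param truth list as returned by `make_tuning()` (fields `preferred`,
#'   `depth_sbp`, `baseline_sbp`, `rate_bin`, `depth_tx`).
#' @param config a `synth_config`.
#' @param start_time start time of the first bin, seconds.
#' @return a [feature_series()].
#' @export
simulate_tuned_features <- function(velocity, truth, config, start_time = 0) {
  if (!is.matrix(velocity) || nrow(velocity) != 2L)
    stop("`velocity` must be a 2 x n matrix")
  if (any(!is.finite(velocity))) stop("`velocity` must be finite")
  n <- ncol(velocity)
  nc <- nrow(truth$preferred)
  proj <- truth$preferred %*% velocity            # channels x bins
  sbp <- truth$baseline_sbp + truth$depth_sbp * proj
  if (config$noise_sd > 0)
    sbp <- sbp + matrix(stats::rnorm(nc * n, 0, config$noise_sd), nc, n)
  lam <- truth$rate_bin * pmax(0, 1 + truth$depth_tx * proj)
  tx <- matrix(stats::rpois(nc * n, lam), nc, n)
  vals <- matrix(0, 2L * nc, n)
  vals[seq(1L, 2L * nc, by = 2L), ] <- sbp
  vals[seq(2L, 2L * nc, by = 2L), ] <- tx
  feature_series(vals, config$bin_width, start_time)
}

#' Noise-free feature footprint of one target-sequence execution
#'
#' The deviation-from-baseline feature pattern evoked by a clean, unit-speed
#' execution of the target sequence (the additive payload used by
#' [embed_replay()]). Spike-band rows carry `depth_c * (d_c . v_t)`;
#' threshold-crossing rows carry the matching rate deviation.
#'
#' @param truth tuning list from `make_tuning()`.
#' @param config a `synth_config`.
#' @param sequence integer vector: order in which the four targets are hit.
#' @return features x bins matrix of deviations (baseline excluded).
#' @export
replay_pattern <- function(truth, config, sequence) {
  v <- sequence_velocity(sequence, config)
  nc <- nrow(truth$preferred)
  proj <- truth$preferred %*% v
  pat <- matrix(0, 2L * nc, ncol(v))
  pat[seq(1L, 2L * nc, by = 2L), ] <- truth$depth_sbp * proj
  pat[seq(2L, 2L * nc, by = 2L), ] <- truth$rate_bin * truth$depth_tx * proj
  pat
}

# intended-velocity profile of executing `sequence` (one unit-speed leg per
# target, no demonstration period), as a 2 x bins matrix
sequence_velocity <- function(sequence, cfg) {
  ang <- task_target_angles()[sequence]
  bins_leg <- round(cfg$leg_duration / cfg$bin_width)
  vx <- rep(cos(ang), each = bins_leg)
  vy <- rep(sin(ang), each = bins_leg)
  rbind(vx, vy)
}

#' Inject replay events into a background feature series
#'
#' At each scheduled time, the pattern is resampled in time by `1 / tau`
#' (linear interpolation on the bin grid, footprint `round(L / tau)` bins),
#' scaled by `amplitude`, and added onto the background. Background
#' statistics outside the injected windows are untouched.
#'
#' @param features background [feature_series()].
#' @param pattern features x bins matrix of deviations (see
#'   [replay_pattern()]); must be shorter than the feature segment.
#' @param schedule data.frame with columns `time` (absolute seconds), `tau`,
#'   `amplitude`.
#' @return list with elements `features` (modified series) and `events`
#'   ([event_table()] of kind `"injected"` holding the exact footprints).
#' @export
embed_replay <- function(features, pattern, schedule) {
  stopifnot(inherits(features, "feature_series"), is.matrix(pattern))
  if (nrow(pattern) != nrow(features$values))
    stop("pattern and features must have the same feature count")
  if (ncol(pattern) >= ncol(features$values))
    stop("pattern must be shorter than the target segment")
  if (nrow(schedule) == 0)
    return(list(features = features, events = event_table()))
  if (any(schedule$tau <= 0)) stop("tau must be > 0")
  bw <- features$bin_width
  n <- ncol(features$values)
  Lp <- ncol(pattern)
  vals <- features$values
  ev_time <- ev_dur <- numeric(nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    tau <- schedule$tau[i]
    Lj <- max(2L, round(Lp / tau))
    b0 <- 1L + round((schedule$time[i] - features$start_time) / bw)
    if (b0 < 1L || b0 + Lj - 1L > n)
      stop(sprintf("injection at t=%g s overlaps the segment end",
                   schedule$time[i]))
    src <- seq(1, Lp, length.out = Lj)
    lo <- floor(src); hi <- pmin(Lp, lo + 1L); w <- src - lo
    pat_j <- pattern[, lo, drop = FALSE] * rep(1 - w, each = nrow(pattern)) +
      pattern[, hi, drop = FALSE] * rep(w, each = nrow(pattern))
    idx <- b0:(b0 + Lj - 1L)
    vals[, idx] <- vals[, idx] + schedule$amplitude[i] * pat_j
    ev_time[i] <- features$start_time + (b0 - 1L) * bw
    ev_dur[i] <- Lj * bw
  }
  ord <- order(ev_time)
  out_fs <- feature_series(vals, bw, features$start_time,
                           features$channel_meta, features$feature_meta)
  ev <- event_table(time = ev_time[ord], duration = ev_dur[ord],
                    kind = "injected",
                    label = sprintf("tau=%g", schedule$tau[ord]),
                    tau = schedule$tau[ord],
                    amplitude = schedule$amplitude[ord])
  list(features = out_fs, events = ev)
}

#' Simulate single-channel scalp EEG from a stage schedule
#'
#' Slow-wave epochs are dominated by 0.5-4 Hz power, wake and non-slow-wave
#' epochs by 8-30 Hz power (band-filtered Gaussian noise, third-order
#' Butterworth). Three positive tap pulses are superimposed at the start of
#' the recording as the clock-sync artifact.
#'
#' @param stage_schedule data.frame with columns `onset` (seconds,
#'   intracortical clock), `duration`, `stage` (`"wake"`, `"sws"`, `"nsws"`).
#' @param config a `synth_config` (uses `eeg_rate`, `eeg_clock_offset`).
#' @param sync_taps add the 3-tap artifact at recording start?
#' @return an [eeg_recording()] (raw, unfiltered flag).
#' @export
simulate_eeg <- function(stage_schedule, config, sync_taps = TRUE) {
  fs <- config$eeg_rate
  if (nrow(stage_schedule) == 0 || sum(stage_schedule$duration) <= 0)
    return(eeg_recording(numeric(0), fs,
                         start_time = config$eeg_clock_offset))
  amps <- list(sws = c(delta = 60, fast = 2.5),
               nsws = c(delta = 4, fast = 20),
               wake = c(delta = 3, fast = 25))
  bands <- list(delta = c(0.5, 2), fast = c(8, 30))
  bp <- function(x, band) {
    bf <- signal::butter(3, band / (fs / 2), type = "pass")
    signal::filtfilt(bf, x)
  }
  segs <- lapply(seq_len(nrow(stage_schedule)), function(i) {
    ns <- round(stage_schedule$duration[i] * fs)
    if (ns <= 0) return(numeric(0))
    a <- amps[[stage_schedule$stage[i]]]
    if (is.null(a)) stop("unknown stage: ", stage_schedule$stage[i])
    # scale compensates band-pass attenuation of white noise
    a[["delta"]] * 11 * bp(stats::rnorm(ns), bands$delta) +
      a[["fast"]] * 3.2 * bp(stats::rnorm(ns), bands$fast)
  })
  x <- unlist(segs)
  if (sync_taps && length(x) > 4 * fs) {
    tap <- 300 * exp(-((seq_len(round(0.05 * fs)) - 1) / (0.01 * fs))^2)
    for (t0 in c(1, 2, 3)) {
      i0 <- round(t0 * fs)
      x[i0:(i0 + length(tap) - 1L)] <- x[i0:(i0 + length(tap) - 1L)] + tap
    }
  }
  eeg_recording(x, fs,
                start_time = stage_schedule$onset[1] + config$eeg_clock_offset)
}

#' Simulate medial-array LFP with ripple bursts over the sleep segment
#'
#' Background is low-passed Gaussian noise at 1 kHz. Each injected replay
#' event is accompanied (with probability `ripple_coupling$prob`) by an
#' 80 Hz burst of ~120 ms on a random subset of channels, centered at the
#' configured lag after injection onset; additional uncoupled bursts are
#' scattered at a low rate.
#'
#' @param injected [event_table()] of injected replay events.
#' @param config a `synth_config`.
#' @param sleep_start,sleep_end sleep segment limits, seconds.
#' @param rate sampling rate (Hz), natively 1000.
#' @param uncoupled_rate_hz rate of background ripple bursts per channel.
#' @return list of class `lfp_recording`: `values` (channels x samples),
#'   `rate`, `start_time`, `channels`.
#' @export
simulate_lfp <- function(injected, config, sleep_start, sleep_end,
                         rate = 1000, uncoupled_rate_hz = 1 / 120) {
  nch <- config$n_lfp_channels
  ns <- round((sleep_end - sleep_start) * rate)
  lp <- signal::butter(4, 30 / (rate / 2), type = "low")
  vals <- matrix(0, nch, ns)
  for (c in seq_len(nch))
    vals[c, ] <- signal::filtfilt(lp, stats::rnorm(ns, 0, 10))
  burst <- function(center_s, chans, amp) {
    dur <- 0.12
    i0 <- round((center_s - sleep_start - dur / 2) * rate)
    ii <- i0:(i0 + round(dur * rate))
    ok <- ii >= 1 & ii <= ns
    ii <- ii[ok]
    if (length(ii) < 2) return(invisible())
    tt <- (ii - ii[1]) / rate
    env <- sin(pi * tt / max(tt))^2
    for (c in chans)
      vals[c, ii] <<- vals[c, ii] + amp * env * sin(2 * pi * 80 * tt +
                                                      stats::runif(1, 0, 2 * pi))
  }
  if (nrow(injected) > 0) {
    for (i in seq_len(nrow(injected))) {
      if (stats::runif(1) > config$ripple_coupling$prob) next
      lag <- config$ripple_coupling$lag
      lag <- if (identical(lag, "mid")) injected$duration[i] / 2 else lag
      k <- sample(4:nch, 1L)
      burst(injected$time[i] + lag, sample(seq_len(nch), k), amp = 60)
    }
  }
  n_unc <- stats::rpois(1, uncoupled_rate_hz * (sleep_end - sleep_start) * nch)
  if (n_unc > 0) {
    for (i in seq_len(n_unc))
      burst(stats::runif(1, sleep_start + 1, sleep_end - 1),
            sample(seq_len(nch), sample(1:4, 1)), amp = 50)
  }
  structure(list(values = vals, rate = rate, start_time = sleep_start,
                 channels = seq_len(nch)),
            class = "lfp_recording")
}

#' Simulate one full synthetic recording session
#'
#' Emulates the session timeline: clock-sync, center-out calibration block,
#' pre-task rest, task blocks of the sequence-matching memory game,
#' post-task rest, and an overnight sleep segment with alternating
#' slow-wave / non-slow-wave epochs into which ground-truth replay of the
#' target sequence is injected per `config$replay_schedule`. All streams
#' share the intracortical clock (the EEG stream is offset by
#' `eeg_clock_offset` to emulate the second device clock). Fully
#' reproducible from `config$seed`.
#'
#' @param config a `synth_config`.
#' @param lfp also synthesize overnight LFP (memory-heavy; default FALSE,
#'   see [simulate_lfp()]).
#' @return list of class `synth_session` with elements `features`
#'   ([feature_series()]), `events` ([event_table()]), `eeg`
#'   ([eeg_recording()]), `truth` (ground truth: injected events, stage
#'   schedule, tuning, intended velocity), `epochs` (data.frame of named
#'   segments), `neural_sync` (1 kHz marker series with the square-wave
#'   sync impulse), optionally `lfp`, and `config`.
#' @export
simulate_session <- function(config, lfp = FALSE) {
  validate_config(config)
  if (!is.numeric(config$seed)) stop("invalid config field `seed`")
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(config$seed)
  bw <- config$bin_width
  tuning <- make_tuning(config)

  # ---- timeline ----------------------------------------------------------
  t <- 5                                    # sync routine occupies [0, 5)
  cal_len <- 3
  cal_gap <- 0.5
  n_cal <- max(8L, floor(config$calib_duration / (cal_len + cal_gap)))
  cal_ang <- calib_angles()[(seq_len(n_cal) - 1L) %% 8L + 1L]
  cal_start <- t + (seq_len(n_cal) - 1L) * (cal_len + cal_gap)
  t_cal_end <- t + config$calib_duration
  rest1 <- c(t_cal_end, t_cal_end + config$rest_duration)

  trial_len <- config$sequence_length * config$leg_duration
  trial_pitch <- config$demo_duration + trial_len + config$trial_gap
  block_gap <- 10
  n_trials <- config$n_blocks * config$trials_per_block
  task_start <- rest1[2]
  trial_rows <- list()
  tt <- task_start
  target_seq <- c(1L, 3L, 2L, 4L)[seq_len(min(4L, config$sequence_length))]
  if (config$sequence_length > 4L)
    target_seq <- ((seq_len(config$sequence_length) - 1L) %% 4L) + 1L
  perms4 <- perms_of_four()
  for (b in seq_len(config$n_blocks)) {
    is_target <- sample(rep(c(TRUE, FALSE),
                            c(config$target_per_block,
                              config$trials_per_block -
                                config$target_per_block)))
    for (k in seq_len(config$trials_per_block)) {
      sq <- if (is_target[k]) target_seq else {
        repeat {
          cand <- perms4[sample(nrow(perms4), 1L), seq_len(4L)]
          cand <- cand[seq_len(min(4L, config$sequence_length))]
          if (!identical(as.integer(cand), as.integer(target_seq))) break
        }
        cand
      }
      p_s <- if (is_target[k]) config$success_rate_target else
        config$success_rate_distractor
      trial_rows[[length(trial_rows) + 1L]] <- data.frame(
        time = tt + config$demo_duration, duration = trial_len,
        label = if (is_target[k]) "target" else "distractor",
        success = stats::runif(1) < p_s,
        seq = paste(sq, collapse = "-"))
      tt <- tt + trial_pitch
    }
    tt <- tt + block_gap
  }
  trials <- do.call(rbind, trial_rows)
  task_end <- tt
  rest2 <- c(task_end, task_end + config$rest_duration)
  sleep <- c(rest2[2], rest2[2] + config$sleep_duration)
  n_bins <- ceiling(sleep[2] / bw)

  # ---- intended velocity -------------------------------------------------
  v <- matrix(0, 2, n_bins)
  put_leg <- function(t0, dur, ang) {
    b <- (round(t0 / bw) + 1L):min(n_bins, round((t0 + dur) / bw))
    v[1, b] <<- cos(ang); v[2, b] <<- sin(ang)
  }
  for (i in seq_len(n_cal)) put_leg(cal_start[i], cal_len, cal_ang[i])
  for (i in seq_len(nrow(trials))) {
    sq <- as.integer(strsplit(trials$seq[i], "-")[[1]])
    n_legs <- if (trials$success[i]) length(sq) else
      sample(seq_len(max(1L, length(sq) - 1L)), 1L)
    for (k in seq_len(n_legs))
      put_leg(trials$time[i] + (k - 1L) * config$leg_duration,
              config$leg_duration, task_target_angles()[sq[k]])
  }

  # ---- features + injections --------------------------------------------
  features <- simulate_tuned_features(v, tuning, config, start_time = 0)
  sched <- config$replay_schedule
  injected <- event_table()
  if (nrow(sched) > 0) {
    sched_abs <- sched
    sched_abs$time <- sleep[1] + sched$time
    pat <- replay_pattern(tuning, config, target_seq)
    emb <- embed_replay(features, pat, sched_abs)
    features <- emb$features
    injected <- emb$events
  }

  # ---- EEG ---------------------------------------------------------------
  ep <- sws_epochs(config)
  stage_rows <- data.frame(onset = 0, duration = sleep[1], stage = "wake")
  if (config$sleep_duration > 0) {
    cur <- sleep[1]
    while (cur < sleep[2] - 1e-9) {
      d_sws <- min(config$sws_cycle[["sws"]], sleep[2] - cur)
      stage_rows <- rbind(stage_rows,
                          data.frame(onset = cur, duration = d_sws,
                                     stage = "sws"))
      cur <- cur + d_sws
      if (cur >= sleep[2] - 1e-9) break
      d_n <- min(config$sws_cycle[["nsws"]], sleep[2] - cur)
      stage_rows <- rbind(stage_rows,
                          data.frame(onset = cur, duration = d_n,
                                     stage = "nsws"))
      cur <- cur + d_n
    }
  }
  eeg <- simulate_eeg(stage_rows, config)

  # ---- sync marker on the intracortical side (square-wave impulse) ------
  sync_rate <- 1000
  sync_n <- round(30 * sync_rate)
  sync_samples <- stats::rnorm(sync_n, 0, 1)
  imp <- (round(1 * sync_rate)):(round(1.5 * sync_rate))
  sync_samples[imp] <- sync_samples[imp] + 100
  neural_sync <- list(samples = sync_samples, rate = sync_rate,
                      start_time = 0)

  # ---- event table -------------------------------------------------------
  cal_ev <- event_table(time = cal_start, duration = cal_len, kind = "trial",
                        label = "calibration", success = TRUE,
                        target_x = cos(cal_ang), target_y = sin(cal_ang))
  task_ev <- event_table(time = trials$time, duration = trials$duration,
                         kind = "trial", label = trials$label,
                         success = trials$success, seq = trials$seq)
  sync_ev <- event_table(time = c(0, sleep[1]), duration = 5, kind = "sync",
                         label = "tap3")
  events <- bind_events(cal_ev, task_ev, sync_ev, injected)

  epochs <- data.frame(
    name = c("calibration", "rest_pre", "task", "rest_post", "sleep"),
    start = c(t, rest1[1], task_start, rest2[1], sleep[1]),
    end = c(t_cal_end, rest1[2], task_end, rest2[2], sleep[2]))

  truth <- list(injected_events = injected, stage_schedule = stage_rows,
                preferred_directions = tuning$preferred, tuning = tuning,
                intended_velocity = v, target_sequence = target_seq)

  out <- list(features = features, events = events, eeg = eeg,
              truth = truth, epochs = epochs, neural_sync = neural_sync,
              config = config)
  if (lfp)
    out$lfp <- simulate_lfp(injected, config, sleep[1], sleep[2])
  class(out) <- "synth_session"
  out
}

#' @export
print.synth_session <- function(x, ...) {
  cat(sprintf("<synth_session> %d channels, %.0f s, %d events (%d injected)\n",
              x$config$n_channels, max(x$epochs$end), nrow(x$events),
              nrow(x$truth$injected_events)))
  invisible(x)
}

# all 24 permutations of 1:4
perms_of_four <- function() {
  p <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  p <- p[apply(p, 1, function(r) length(unique(r)) == 4L), ]
  as.matrix(p)
}
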