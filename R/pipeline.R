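#' Per-category trial success summary
#'
#' Success counts and percentages per trial category (target / distractor).
#'
#' @param trials [event_table()] with labeled task trials.
#' @return data.frame: `label`, `n_success`, `n_trials`, `pct` (percent,
#'   full precision; print rounds to 1 dp).
#' @export
summarize_performance <- function(trials) {
  use <- trials$kind == "trial" & trials$label %in% c("target", "distractor")
  trials <- trials[use, , drop = FALSE]
  labs <- unique(trials$label)
  rows <- lapply(labs, function(l) {
    sub <- trials[trials$label == l, , drop = FALSE]
    ns <- sum(sub$success, na.rm = TRUE)
    data.frame(label = l, n_success = ns, n_trials = nrow(sub),
               pct = 100 * ns / nrow(sub))
  })
  do.call(rbind, rows)
}

#' Event rates per epoch
#'
#' Rate = count / epoch duration in hours. Zero-duration epochs yield an
#' `NA` rate with a flag rather than an error.
#'
#' @param event_times event onsets, seconds.
#' @param epochs data.frame with `name`, `start`, `end` (seconds).
#' @return data.frame: `name`, `n_events`, `hours`, `rate_per_h`,
#'   `undefined`.
#' @export
epoch_rates <- function(event_times, epochs) {
  rows <- lapply(seq_len(nrow(epochs)), function(i) {
    n <- sum(event_times >= epochs$start[i] & event_times < epochs$end[i])
    h <- (epochs$end[i] - epochs$start[i]) / 3600
    data.frame(name = epochs$name[i], n_events = n, hours = h,
               rate_per_h = if (h > 0) n / h else NA_real_,
               undefined = h <= 0)
  })
  do.call(rbind, rows)
}

# deterministic per-stage child seed from the master seed and stage name
child_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h) %% 2147483647)
}

#' Run the full replay-detection pipeline on a synthetic session
#'
#' Executes all stages in dependency order: simulate, calibrate, decode,
#' build templates, optimize thresholds by Youden's J, detect STCEs per
#' epoch, firing-order matching with the random control, the two bootstrap
#' nulls, the temporal-compression sweep, EEG sleep staging with SWS
#' enrichment, and (optionally) ripple detection and STCE-ripple
#' alignment. Every stochastic stage consumes a named child seed derived
#' from the master seed.
#'
#' @param config a `synth_config` (its `seed` is the master seed).
#' @param percentiles integer percentiles scanned for the threshold.
#' @param n_features decoder features to select (capped at the number of
#'   available features).
#' @param taus compression factors for the sweep.
#' @param n_null bootstrap iterations for each null (default 100).
#' @param stages character vector of optional stages to run; subset of
#'   `c("seqmatch", "nulls", "tau_sweep", "sleep", "ripples")`.
#' @param control_pairs random-sequence pairs for the matching control.
#' @return a list of class `run_report`.
#' @export
run_pipeline <- function(config,
                         percentiles = 90:99,
                         n_features = 40L,
                         taus = c(0.5, 1, 2, 4),
                         n_null = 100L,
                         stages = c("seqmatch", "nulls", "tau_sweep",
                                    "sleep"),
                         control_pairs = 20000L) {
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  session <- run_stage("simulate",
                       simulate_session(config, lfp = "ripples" %in% stages))
  ep <- session$epochs
  epoch <- function(nm) ep[ep$name == nm, ]
  cal <- epoch("calibration")

  model <- run_stage("calibrate", {
    cues <- session$events[session$events$label == "calibration", ]
    calibrate(fs_window(session$features, cal$start, cal$end), cues,
              n_features = min(n_features, nrow(session$features$values)))
  })
  traj <- run_stage("decode", decode(session$features, model))

  trials <- session$events[session$events$kind == "trial" &
                             session$events$label %in%
                             c("target", "distractor"), ]
  task <- epoch("task")
  traj_task <- traj_window(traj, task$start, task$end)
  template <- run_stage("templates", build_templates(traj_task, trials))

  thr <- run_stage("thresholds", {
    optimize_threshold(sliding_correlation(traj_task, template), trials,
                       percentiles)
  })

  sleep <- epoch("sleep")
  traj_sleep <- traj_window(traj, sleep$start, sleep$end)
  corr_sleep <- sliding_correlation(traj_sleep, template)
  det_sleep <- detect_stce(corr_sleep, thr$threshold_x, thr$threshold_y)

  stce_all <- lapply(seq_len(nrow(ep)), function(i) {
    tw <- traj_window(traj, ep$start[i], ep$end[i])
    if (length(tw$x) <= length(template$x_template)) return(event_table())
    detect_stce(sliding_correlation(tw, template),
                thr$threshold_x, thr$threshold_y)$events
  })
  stce_events <- do.call(bind_events, stce_all)
  rates <- epoch_rates(stce_events$time, ep)

  report <- list(
    config = config, epochs = ep, model = model, template = template,
    thresholds = thr, performance = summarize_performance(trials),
    stce_events = stce_events, rates = rates,
    sleep_stces = det_sleep$events,
    injected = session$truth$injected_events,
    seed_registry = list(master = config$seed))

  if ("seqmatch" %in% stages) {
    report$seqmatch <- run_stage("seqmatch", {
      succ <- trials[trials$label == "target" & trials$success, ]
      task_orders <- lapply(succ$time, function(t0)
        peak_firing_order(session$features, t0))
      night_orders <- if (nrow(det_sleep$events) >= 1)
        lapply(det_sleep$events$time, function(t0)
          peak_firing_order(session$features, t0))
      else list()
      ctrl <- random_matching_control(control_pairs,
                                      sum(session$features$channel_meta$array
                                          == "medial"),
                                      seed = child_seed(config$seed,
                                                        "control"))
      res <- list(control = ctrl)
      if (length(task_orders) >= 2)
        res$task_vs_task <- matching_index_distribution(task_orders,
                                                        control = ctrl)
      if (length(night_orders) >= 1 && length(task_orders) >= 1)
        res$task_vs_night <- matching_index_distribution(task_orders,
                                                         night_orders,
                                                         control = ctrl)
      res
    })
  }

  if ("nulls" %in% stages) {
    report$nulls <- run_stage("nulls", {
      rest1 <- epoch("rest_pre")
      traj_rest <- traj_window(traj, rest1$start, rest1$end)
      obs <- nrow(det_sleep$events)
      list(
        pseudo = pseudo_template_control(
          traj_rest, traj_task, traj_sleep,
          length(template$x_template), percentile = thr$percentile,
          n = n_null, seed = child_seed(config$seed, "pseudo"),
          observed = obs),
        phase = phase_randomized_control(
          traj_sleep, template, thr$threshold_x, thr$threshold_y,
          n = n_null, seed = child_seed(config$seed, "phase"),
          observed = obs))
    })
  }

  if ("tau_sweep" %in% stages) {
    report$tau_sweep <- run_stage("tau_sweep",
      compression_sweep(traj_sleep, template, taus,
                        thr$threshold_x, thr$threshold_y))
  }

  if ("sleep" %in% stages) {
    report$sleep <- run_stage("sleep", {
      eeg_f <- preprocess_eeg(session$eeg)
      # move the EEG onto the intracortical clock via the sync offset
      offset <- tryCatch(align_clocks(session$neural_sync, eeg_f),
                         error = function(e) config$eeg_clock_offset)
      eeg_f$start_time <- eeg_f$start_time - offset
      night <- eeg_window(eeg_f, sleep$start, sleep$end)
      stages_series <- sleep_stage_series(night)
      list(stages = stages_series,
           enrichment = sws_enrichment(det_sleep$events, stages_series),
           clock_offset = offset)
    })
  }

  if ("ripples" %in% stages && !is.null(session$lfp)) {
    report$ripples <- run_stage("ripples", {
      rip <- ripple_table(session$lfp)
      align <- stce_ripple_alignment(det_sleep$events$time, rip)
      xc <- stce_ripple_crosscorr(corr_sleep, rip, det_sleep$events$time)
      list(table = rip, alignment = align, crosscorr = xc)
    })
  }

  class(report) <- "run_report"
  report
}

# clip an EEG recording to a time window on its own clock
eeg_window <- function(eeg, from, to) {
  i0 <- max(1L, round((from - eeg$start_time) * eeg$rate) + 1L)
  i1 <- min(length(eeg$samples), round((to - eeg$start_time) * eeg$rate))
  if (i1 < i0) stop("window outside the recording")
  eeg_recording(eeg$samples[i0:i1], eeg$rate,
                start_time = eeg$start_time + (i0 - 1L) / eeg$rate,
                filtered = eeg$filtered)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  threshold percentile %d (J = %.2f)\n",
              x$thresholds$percentile, x$thresholds$youden_j))
  r <- x$rates
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %-12s %3d STCEs in %5.2f h (%s/h)\n", r$name[i],
                r$n_events[i], r$hours[i],
                ifelse(r$undefined[i], "NA", sprintf("%.2f",
                                                     r$rate_per_h[i]))))
  invisible(x)
}

#' Serialize a run report to a JSON + CSV bundle
#'
#' Writes `report.json` (summary scalars and tables) and CSV files for the
#' event tables into `dir`.
#'
#' @param report a `run_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(
    schema = "sleepreplay/run_report/1",
    percentile = report$thresholds$percentile,
    youden_j = report$thresholds$youden_j,
    thresholds = c(report$thresholds$threshold_x,
                   report$thresholds$threshold_y),
    rates = report$rates,
    performance = report$performance,
    seed_registry = report$seed_registry)
  if (!is.null(report$nulls))
    summary$nulls <- list(
      pseudo_p = report$nulls$pseudo$p_value,
      phase_p_t = report$nulls$phase$p_t,
      phase_p_empirical = report$nulls$phase$p_empirical)
  if (!is.null(report$tau_sweep))
    summary$tau_sweep <- report$tau_sweep
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  write_event_table(report$stce_events, file.path(dir, "stces.csv"))
  write_event_table(report$injected, file.path(dir, "injected.csv"))
  invisible(dir)
}
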