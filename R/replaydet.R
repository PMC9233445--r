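#' Build X/Y trajectory templates from successful target trials
#'
#' Each successful target trial's decoded X and Y segments are mean-centered
#' (sliding correlation matching is offset-invariant and the raw offline
#' position carries an arbitrary slow offset), linearly resampled to the
#' median trial length in bins, and averaged pointwise; the per-bin SEM is
#' retained.
#'
#' @param traj a [trajectory_series()] covering the task blocks.
#' @param trials [event_table()] of task trials (label `"target"`,
#'   `success == TRUE` rows are used).
#' @return a list of class `template_pair`: `x_template`, `y_template`,
#'   `sem_x`, `sem_y`, `duration`, `tau` (1 for native), `n_trials`,
#'   `bin_width`.
#' @export
build_templates <- function(traj, trials) {
  stopifnot(inherits(traj, "trajectory_series"))
  use <- trials$kind == "trial" & trials$label == "target" &
    !is.na(trials$success) & trials$success
  trials <- trials[use, , drop = FALSE]
  if (nrow(trials) == 0) stop("no successful target trials to average")
  tt <- traj$start_time + (seq_along(traj$x) - 1L) * traj$bin_width
  segs <- lapply(seq_len(nrow(trials)), function(i) {
    b <- which(tt >= trials$time[i] - 1e-9 &
                 tt < trials$time[i] + trials$duration[i] - 1e-9)
    if (length(b) < 2) return(NULL)
    list(x = traj$x[b] - mean(traj$x[b]), y = traj$y[b] - mean(traj$y[b]))
  })
  segs <- Filter(Negate(is.null), segs)
  if (length(segs) == 0) stop("no trial segments overlap the trajectory")
  L <- stats::median(vapply(segs, function(s) length(s$x), 0))
  L <- as.integer(round(L))
  resamp <- function(z) {
    if (length(z) == L) return(z)
    stats::approx(seq(0, 1, length.out = length(z)), z,
                  seq(0, 1, length.out = L))$y
  }
  Xm <- vapply(segs, function(s) resamp(s$x), numeric(L))
  Ym <- vapply(segs, function(s) resamp(s$y), numeric(L))
  Xm <- matrix(Xm, nrow = L); Ym <- matrix(Ym, nrow = L)
  k <- ncol(Xm)
  sem <- function(M) if (k > 1) apply(M, 1, stats::sd) / sqrt(k) else
    rep(0, L)
  structure(
    list(x_template = rowMeans(Xm), y_template = rowMeans(Ym),
         sem_x = sem(Xm), sem_y = sem(Ym),
         duration = L * traj$bin_width, tau = 1, n_trials = k,
         bin_width = traj$bin_width),
    class = "template_pair")
}

#' @export
print.template_pair <- function(x, ...) {
  cat(sprintf(
    "<template_pair> %d bins (%.2f s), tau = %g, averaged over %d trials\n",
    length(x$x_template), x$duration, x$tau, x$n_trials))
  invisible(x)
}

# rolling window sums via cumulative sums: out[t] = sum(x[t..t+L-1])
roll_sum <- function(x, L) {
  cs <- cumsum(x)
  cs[L:length(x)] - c(0, cs[seq_len(length(x) - L)])
}

# cross-correlation sums out[t] = sum_k x[t+k-1] * tmpl[k] via FFT
cross_sum_fft <- function(x, tmpl) {
  n <- length(x); L <- length(tmpl)
  N <- stats::nextn(n + L, 2)
  X <- stats::fft(c(x, numeric(N - n)))
  Tm <- stats::fft(c(tmpl, numeric(N - L)))
  r <- Re(stats::fft(X * Conj(Tm), inverse = TRUE)) / N
  r[seq_len(n - L + 1L)]
}

# sliding Pearson correlation of every length-L window of x with tmpl;
# zero-variance windows (or template) map to 0; clipped to [-1, 1]
sliding_pearson <- function(x, tmpl) {
  n <- length(x); L <- length(tmpl)
  s_t <- sum(tmpl); ss_t <- sum(tmpl^2)
  var_t <- ss_t - s_t^2 / L
  S_x <- roll_sum(x, L)
  S_xx <- roll_sum(x^2, L)
  S_xy <- cross_sum_fft(x, tmpl)
  var_x <- pmax(0, S_xx - S_x^2 / L)
  num <- S_xy - S_x * s_t / L
  den <- sqrt(var_x * var_t)
  scale_ref <- max(var_x, var_t, 1e-300)
  r <- ifelse(var_x <= 1e-12 * scale_ref | var_t <= 0, 0, num / den)
  pmin(1, pmax(-1, r))
}

#' Sliding correlation between a trajectory and a template pair
#'
#' For each start bin `t`, the Pearson correlation between the template and
#' the trajectory window `[t, t + L)` is computed per spatial dimension
#' ("cross-correlation" in the sliding-window sense; values bounded in
#' `[-1, 1]`). The series is truncated at the last full window;
#' zero-variance windows yield 0.
#'
#' @param traj a [trajectory_series()].
#' @param template a `template_pair` (possibly dilated).
#' @return a list of class `correlation_series`: `cc_x`, `cc_y`, `L`,
#'   `bin_width`, `start_time` (correlation at `t` refers to window
#'   `[t, t + L)`).
#' @export
sliding_correlation <- function(traj, template) {
  L <- length(template$x_template)
  if (L > length(traj$x))
    stop("template longer than the trajectory")
  structure(
    list(cc_x = sliding_pearson(traj$x, template$x_template),
         cc_y = sliding_pearson(traj$y, template$y_template),
         L = L, bin_width = traj$bin_width, start_time = traj$start_time),
    class = "correlation_series")
}

#' @export
print.correlation_series <- function(x, ...) {
  cat(sprintf("<correlation_series> %d windows of %d bins, t0 = %g s\n",
              length(x$cc_x), x$L, x$start_time))
  invisible(x)
}

#' Detect simultaneous threshold crossing events (STCEs)
#'
#' Bins where both `cc_x >= thr_x` and `cc_y >= thr_y` are marked; runs of
#' contiguous marked bins collapse to a single event timestamped at the
#' run's first bin (the event denotes the start of the following L-bin
#' trajectory).
#'
#' @param corr a `correlation_series`.
#' @param thr_x,thr_y correlation thresholds in (-1, 1).
#' @return a list of class `stce_result` with `events` ([event_table()],
#'   kind `"stce"`), `threshold_x`, `threshold_y`.
#' @export
detect_stce <- function(corr, thr_x, thr_y) {
  stopifnot(inherits(corr, "correlation_series"))
  marked <- corr$cc_x >= thr_x & corr$cc_y >= thr_y
  ev <- event_table()
  if (any(marked)) {
    r <- rle(marked)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    first_bins <- starts[r$values]
    ev <- event_table(
      time = corr$start_time + (first_bins - 1L) * corr$bin_width,
      duration = corr$L * corr$bin_width, kind = "stce", label = "stce")
  }
  structure(list(events = ev, threshold_x = thr_x, threshold_y = thr_y,
                 percentile = NA_integer_, youden_j = NA_real_),
            class = "stce_result")
}

#' @export
print.stce_result <- function(x, ...) {
  cat(sprintf(
    "<stce_result> %d events, thr = (%.4f, %.4f), percentile = %s, J = %s\n",
    nrow(x$events), x$threshold_x, x$threshold_y,
    format(x$percentile), format(round(x$youden_j, 3))))
  invisible(x)
}

#' Youden's J statistic from classification counts
#'
#' `J = sensitivity + specificity - 1
#'    = hits / n_target + (n_other - false_alarms) / n_other - 1`.
#'
#' @param hits successful target trials correctly identified by an STCE.
#' @param n_target number of successful target trials.
#' @param false_alarms STCE-containing other trials (or stray STCEs).
#' @param n_other number of other trials.
#' @return Youden's J.
#' @export
youden_j <- function(hits, n_target, false_alarms, n_other) {
  if (n_target <= 0 || n_other <= 0)
    stop("denominators must be positive")
  if (hits < 0 || hits > n_target)
    stop("`hits` must lie in [0, n_target]")
  if (false_alarms < 0)
    stop("`false_alarms` must be non-negative")
  hits / n_target + (n_other - false_alarms) / n_other - 1
}

# classify STCEs against task trials: an STCE identifies the trial whose
# [start, end] span contains the midpoint of its L-bin trajectory footprint
# (the event timestamp marks where the stereotyped trajectory *begins*, so
# a threshold run starting a bin or two before trial onset still belongs to
# that trial); STCEs whose footprint midpoint lies in no trial are stray
# false alarms
classify_stces <- function(stce_events, trials) {
  is_task <- trials$kind == "trial" & trials$label %in% c("target",
                                                          "distractor")
  trials <- trials[is_task, , drop = FALSE]
  succ_target <- trials$label == "target" & !is.na(trials$success) &
    trials$success
  hit_trial <- rep(FALSE, nrow(trials))
  stray <- 0L
  mid <- stce_events$time + stce_events$duration / 2
  for (t0 in mid) {
    j <- which(trials$time <= t0 + 1e-9 &
                 t0 <= trials$time + trials$duration + 1e-9)
    if (length(j) == 0) stray <- stray + 1L
    else hit_trial[j[1]] <- TRUE
  }
  list(hits = sum(hit_trial & succ_target),
       false_alarms = sum(hit_trial & !succ_target) + stray,
       n_target = sum(succ_target),
       n_other = sum(!succ_target))
}

#' Optimize the STCE threshold percentile by Youden's J
#'
#' For each integer percentile, thresholds are the percentile of `cc_x` and
#' `cc_y` over the task-block correlation series; detected STCEs are
#' classified against trials (an STCE identifies the trial whose time span
#' contains it; events inside no trial count as false alarms) and the
#' percentile maximizing `J` is returned, ties to the higher percentile.
#'
#' @param corr a `correlation_series` covering the task blocks.
#' @param trials [event_table()] of labeled task trials.
#' @param percentiles integer percentiles to scan (default 90:99).
#' @return an `stce_result` at the optimal percentile, with a `sweep`
#'   data.frame (percentile, thresholds, counts, J) attached.
#' @export
optimize_threshold <- function(corr, trials, percentiles = 90:99) {
  is_task <- trials$kind == "trial" & trials$label %in% c("target",
                                                          "distractor")
  if (!any(is_task)) stop("no labeled task trials supplied")
  rows <- lapply(percentiles, function(p) {
    tx <- stats::quantile(corr$cc_x, p / 100, names = FALSE)
    ty <- stats::quantile(corr$cc_y, p / 100, names = FALSE)
    det <- detect_stce(corr, tx, ty)
    cl <- classify_stces(det$events, trials)
    data.frame(percentile = p, threshold_x = tx, threshold_y = ty,
               n_stce = nrow(det$events), hits = cl$hits,
               false_alarms = cl$false_alarms, n_target = cl$n_target,
               n_other = cl$n_other,
               youden_j = youden_j(cl$hits, cl$n_target,
                                   min(cl$false_alarms, cl$n_other),
                                   cl$n_other))
  })
  sweep <- do.call(rbind, rows)
  best <- sweep[order(-sweep$youden_j, -sweep$percentile), ][1, ]
  out <- detect_stce(corr, best$threshold_x, best$threshold_y)
  out$percentile <- best$percentile
  out$youden_j <- best$youden_j
  out$sweep <- sweep
  out
}

#' Dilate or compress a template pair by a factor tau
#'
#' Cubic-spline interpolants of the X and Y templates are evaluated on a
#' grid of `round(L / tau)` bins spanning the original duration divided by
#' `tau` (tau = 2 replays the sequence in half the time).
#'
#' @param template a `template_pair`.
#' @param tau temporal dilation/compression factor (> 0).
#' @return the dilated `template_pair` with `tau` recorded.
#' @export
dilate_template <- function(template, tau) {
  if (tau <= 0) stop("tau must be > 0")
  L <- length(template$x_template)
  Lnew <- round(L / tau)
  if (Lnew < 2) stop("dilated template would have fewer than 2 bins")
  if (Lnew == L && tau == 1) return(template)
  t0 <- seq_len(L)
  tn <- seq(1, L, length.out = Lnew)
  template$x_template <- stats::splinefun(t0, template$x_template)(tn)
  template$y_template <- stats::splinefun(t0, template$y_template)(tn)
  template$sem_x <- stats::approx(t0, template$sem_x, tn)$y
  template$sem_y <- stats::approx(t0, template$sem_y, tn)$y
  template$tau <- tau
  template$duration <- Lnew * template$bin_width
  template
}

#' Default temporal-compression grid
#'
#' 18 log-spaced values on `[0.1, 10]`, adjusted to include the replay
#' speeds 1, 2, 3 and 4 exactly.
#'
#' @return numeric vector of 18 tau values.
#' @export
default_tau_grid <- function() {
  g <- exp(seq(log(0.1), log(10), length.out = 18))
  for (v in c(1, 2, 3, 4)) g[which.min(abs(g - v))] <- v
  sort(unique(g))
}

#' Sweep template compression factors and count STCEs
#'
#' Per tau: the template is spline-dilated, the sliding correlation and STCE
#' detection re-run with the session's thresholds, and events counted.
#' Optionally a phase-randomized null is attached per tau.
#'
#' @param traj a [trajectory_series()] (e.g. the overnight epoch).
#' @param template the native (`tau = 1`) `template_pair`.
#' @param taus tau values (default [default_tau_grid()]).
#' @param thr_x,thr_y session correlation thresholds.
#' @param null_spec `NULL`, or a list `list(n = , seed = )` requesting a
#'   phase-randomized null at each tau.
#' @return data.frame with one row per tau: `tau`, `n_stce`, and (with a
#'   null) `null_mean`, `null_sd`, `p_empirical`; detected events attached
#'   as attribute `"events"` (list per tau).
#' @export
compression_sweep <- function(traj, template, taus = default_tau_grid(),
                              thr_x, thr_y, null_spec = NULL) {
  if (length(taus) == 0) stop("taus must be non-empty")
  ev_list <- vector("list", length(taus))
  rows <- lapply(seq_along(taus), function(i) {
    tau <- taus[i]
    tmpl <- dilate_template(template, tau)
    if (length(tmpl$x_template) > length(traj$x)) {
      ev_list[[i]] <<- event_table()
      return(data.frame(tau = tau, n_stce = 0L))
    }
    det <- detect_stce(sliding_correlation(traj, tmpl), thr_x, thr_y)
    ev_list[[i]] <<- det$events
    row <- data.frame(tau = tau, n_stce = nrow(det$events))
    if (!is.null(null_spec)) {
      nd <- phase_randomized_control(traj, tmpl, thr_x, thr_y,
                                     n = null_spec$n,
                                     seed = null_spec$seed + i,
                                     observed = nrow(det$events))
      row$null_mean <- mean(nd$counts)
      row$null_sd <- stats::sd(nd$counts)
      row$p_empirical <- nd$p_empirical
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "events") <- ev_list
  out
}
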