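#' Channel peak-firing order within an event window
#'
#' For each medial-array channel, threshold-crossing counts in the 4 s
#' window after event onset are re-binned (default 100 ms bins from the
#' 20 ms grid) and the index of the bin with maximal rate is taken; ties go
#' to the earliest bin. Channels that are silent throughout the window are
#' flagged.
#'
#' @param features a [feature_series()] containing the window.
#' @param event_time event onset, seconds.
#' @param window window length after onset, seconds (default 4).
#' @param rate_bin firing-rate bin for peak detection, seconds (default 0.1).
#' @param channel_mask optional logical/integer mask restricting the
#'   channels compared (defaults to all medial-array channels).
#' @return a list of class `firing_order`: `peak_bins` (1-based bin index
#'   per channel), `silent` (logical), `n_bins`, `window`, `rate_bin`.
#' @export
peak_firing_order <- function(features, event_time, window = 4,
                              rate_bin = 0.1, channel_mask = NULL) {
  stopifnot(inherits(features, "feature_series"))
  bw <- features$bin_width
  tt <- bin_times(features)
  if (event_time < tt[1] - 1e-9 ||
      event_time + window > tt[length(tt)] + bw + 1e-9)
    stop("the event window exceeds the recording span")
  if (is.null(channel_mask))
    channel_mask <- features$channel_meta$array == "medial"
  chans <- features$channel_meta$channel[channel_mask]
  tx_rows <- which(features$feature_meta$kind == "tx" &
                     features$feature_meta$channel %in% chans)
  b0 <- which(tt >= event_time - 1e-9)[1]
  nb <- round(window / bw)
  M <- features$values[tx_rows, b0:(b0 + nb - 1L), drop = FALSE]
  per <- max(1L, round(rate_bin / bw))
  n_coarse <- nb %/% per
  grp <- rep(seq_len(n_coarse), each = per)[seq_len(n_coarse * per)]
  R <- t(apply(M[, seq_along(grp), drop = FALSE], 1,
               function(r) tapply(r, grp, sum)))
  peak <- apply(R, 1, which.max)
  structure(
    list(peak_bins = as.integer(peak), silent = rowSums(R) == 0,
         n_bins = n_coarse, window = window, rate_bin = rate_bin,
         channels = chans),
    class = "firing_order")
}

#' Matching index between two firing orders
#'
#' Over all channel pairs, pairs with the same sign of peak-time difference
#' in both events are concordant (`m`), pairs with opposite sign discordant
#' (`n`); pairs tied in either event are excluded from both. The matching
#' index is `I_m = (m - n) / (m + n)`, bounded in `[-1, 1]` (equal to
#' Kendall's tau on tie-free orders): identical orders give 1, exactly
#' reversed orders -1.
#'
#' @param a,b `firing_order` objects (or plain numeric peak-time vectors)
#'   with equal channel counts.
#' @return a list of class `matching_index_result`: `i_m`, `m`, `n`,
#'   `ties`, `degenerate` (TRUE when `m + n = 0`, `i_m` then `NA`).
#' @export
matching_index <- function(a, b) {
  pa <- if (inherits(a, "firing_order")) a$peak_bins else as.numeric(a)
  pb <- if (inherits(b, "firing_order")) b$peak_bins else as.numeric(b)
  if (length(pa) != length(pb))
    stop("firing orders must have equal channel counts")
  M <- length(pa)
  ii <- pair_idx(M)
  s <- sign(pa[ii$i] - pa[ii$j]) * sign(pb[ii$i] - pb[ii$j])
  m <- sum(s > 0); n <- sum(s < 0); ties <- sum(s == 0)
  structure(
    list(i_m = if (m + n > 0) (m - n) / (m + n) else NA_real_,
         m = m, n = n, ties = ties, degenerate = m + n == 0),
    class = "matching_index_result")
}

# cached upper-triangle pair indices
pair_idx <- local({
  cache <- new.env(parent = emptyenv())
  function(M) {
    key <- as.character(M)
    if (is.null(cache[[key]])) {
      i <- rep.int(seq_len(M - 1L), (M - 1L):1L)
      j <- unlist(lapply(seq_len(M - 1L), function(k) (k + 1L):M))
      cache[[key]] <- list(i = i, j = j)
    }
    cache[[key]]
  }
})

#' Random-sequence control distribution for the matching index
#'
#' Draws `n_pairs` independent pairs of random permutations of
#' `1:n_channels`, computes the matching index for each, and summarizes the
#' null distribution. Under the null the mean is 0 and the per-pair SD is
#' the Kendall-tau null SD `sqrt(2 (2M + 5) / (9 M (M - 1)))`.
#'
#' @param n_pairs number of random sequence pairs (default 100000).
#' @param n_channels sequence length (default 96).
#' @param seed RNG seed.
#' @return a list: `i_m` (all indices), `mean`, `sd`, `ci_half_width`
#'   (1.96 SD / sqrt(n_pairs)), `t_p` (one-sample t-test p vs 0).
#' @export
random_matching_control <- function(n_pairs = 100000L, n_channels = 96L,
                                    seed = 1L) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(seed)
  M <- n_channels
  ii <- pair_idx(M)
  n_pair_ch <- length(ii$i)
  im <- numeric(n_pairs)
  for (k in seq_len(n_pairs)) {
    a <- sample.int(M); b <- sample.int(M)
    s <- sign(a[ii$i] - a[ii$j]) * sign(b[ii$i] - b[ii$j])
    im[k] <- sum(s) / n_pair_ch       # no ties for permutations
  }
  mu <- mean(im); sdv <- stats::sd(im)
  list(i_m = im, mean = mu, sd = sdv,
       ci_half_width = 1.96 * sdv / sqrt(n_pairs),
       t_p = if (n_pairs > 1) stats::t.test(im)$p.value else NA_real_)
}

#' Mean matching index of event pairs against the random control
#'
#' Computes `I_m` for every pair formed from two event sets (peak firing
#' orders), then a two-sample t-test of these indices against the random
#' control distribution.
#'
#' @param orders_a,orders_b lists of `firing_order` objects; when
#'   `orders_b` is `NULL`, all within-set pairs of `orders_a` are used.
#' @param control output of [random_matching_control()].
#' @return list: `i_m` (per pair), `mean`, `ci_half_width`, `p_vs_control`
#'   (two-sample t-test, one-sided greater), `n_pairs`.
#' @export
matching_index_distribution <- function(orders_a, orders_b = NULL,
                                        control = NULL) {
  pairs <- if (is.null(orders_b)) {
    if (length(orders_a) < 2) stop("need at least two events")
    utils::combn(length(orders_a), 2, simplify = FALSE)
  } else {
    if (length(orders_a) < 1 || length(orders_b) < 1)
      stop("need at least one event per set")
    unlist(lapply(seq_along(orders_a), function(i)
      lapply(seq_along(orders_b), function(j) c(i, j))), recursive = FALSE)
  }
  im <- vapply(pairs, function(p) {
    r <- if (is.null(orders_b)) matching_index(orders_a[[p[1]]],
                                               orders_a[[p[2]]])
    else matching_index(orders_a[[p[1]]], orders_b[[p[2]]])
    r$i_m
  }, 0)
  im <- im[!is.na(im)]
  out <- list(i_m = im, mean = mean(im),
              ci_half_width = if (length(im) > 1)
                1.96 * stats::sd(im) / sqrt(length(im)) else NA_real_,
              n_pairs = length(im))
  if (!is.null(control) && length(im) > 1)
    out$p_vs_control <- stats::t.test(im, control$i_m,
                                      alternative = "greater")$p.value
  out
}
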