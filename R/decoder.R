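#' Steady-state Kalman gain by Riccati fixed-point iteration
#'
#' Iterates `P <- A P A' + W`; `K <- P H' (H P H' + Q)^-1`;
#' `P <- (I - K H) P` until the max-abs change in `K` falls below `tol` or
#' `max_iter` iterations, and returns the converged gain.
#'
#' @param A state transition (d x d).
#' @param W state noise covariance (d x d, symmetric PSD).
#' @param H observation matrix (p x d).
#' @param Q observation noise covariance (p x p, invertible on its support).
#' @param tol convergence tolerance on `K` (default 1e-12).
#' @param max_iter iteration cap (default 10000).
#' @return the steady-state gain `K` (d x p).
#' @export
steady_state_gain <- function(A, W, H, Q, tol = 1e-12, max_iter = 10000L) {
  A <- as.matrix(A); W <- as.matrix(W); H <- as.matrix(H); Q <- as.matrix(Q)
  d <- nrow(A)
  stopifnot(ncol(A) == d, all(dim(W) == d), ncol(H) == d,
            all(dim(Q) == nrow(H)))
  P <- W
  K <- matrix(0, d, nrow(H))
  for (i in seq_len(max_iter)) {
    P <- A %*% P %*% t(A) + W
    S <- H %*% P %*% t(H) + Q
    K_new <- P %*% t(H) %*% solve(S)
    P <- (diag(d) - K_new %*% H) %*% P
    delta <- max(abs(K_new - K))
    K <- K_new
    if (delta < tol) return(K)
  }
  stop(sprintf(
    "steady-state gain did not converge in %d iterations (last delta %.3e)",
    max_iter, delta))
}

#' Calibrate a steady-state Kalman decoder from cued center-out data
#'
#' Intended direction per bin is the unit vector from the center to the cued
#' target. Each feature is regressed on intended direction
#' (`z = b + H d + e`); features are ranked by regression R-squared
#' ("greatest modulation") with ties broken by feature index, and the top
#' `n_features` are selected. `Q` is the diagonal of residual variances,
#' `A = a I`, `W = w I` with `w = (1 - a^2) Var(d)` so that the stationary
#' state prior matches the cue kinematics, and the steady-state gain follows
#' from the Riccati iteration.
#'
#' @param features a [feature_series()] covering the calibration block.
#' @param cues [event_table()] of calibration trials carrying `target_x`,
#'   `target_y` columns; at least 8 distinct directions required.
#' @param n_features number of features to select (default 40).
#' @param a state-transition scalar (default 0.96).
#' @param position_leak per-bin position leak lambda (default 0.995),
#'   stored on the model for [decode()].
#' @return a list of class `kalman_model`.
#' @export
calibrate <- function(features, cues, n_features = 40L, a = 0.96,
                      position_leak = 0.995) {
  stopifnot(inherits(features, "feature_series"))
  cues <- cues[!is.na(cues$target_x) & !is.na(cues$target_y), , drop = FALSE]
  if (nrow(cues) == 0) stop("cues carry no target positions")
  ang <- round(atan2(cues$target_y, cues$target_x), 6)
  if (length(unique(ang)) < 8)
    stop("calibration requires >= 8 distinct cue directions")
  tt <- bin_times(features)
  d <- matrix(NA_real_, 2, ncol(features$values))
  for (i in seq_len(nrow(cues))) {
    b <- tt >= cues$time[i] & tt < cues$time[i] + cues$duration[i]
    u <- c(cues$target_x[i], cues$target_y[i])
    u <- u / sqrt(sum(u^2))
    d[1, b] <- u[1]; d[2, b] <- u[2]
  }
  use <- !is.na(d[1, ])
  if (!any(use)) stop("no feature bins fall inside the cue trials")
  X <- cbind(1, t(d[, use, drop = FALSE]))            # n x 3
  Z <- t(features$values[, use, drop = FALSE])        # n x p
  XtX <- crossprod(X)
  if (kappa(XtX) > 1e10)
    stop("rank-deficient calibration design (cue directions degenerate)")
  beta <- solve(XtX, crossprod(X, Z))                 # 3 x p
  fit <- X %*% beta
  res <- Z - fit
  rss <- colSums(res^2)
  tss <- colSums(scale(Z, scale = FALSE)^2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, 0)
  p <- ncol(Z)
  if (p < n_features)
    stop(sprintf("only %d features available, %d requested", p, n_features))
  sel <- order(-r2, seq_len(p))[seq_len(n_features)]
  if (any(r2[sel] < 0.01))
    warning(sprintf(
      "%d of %d selected features show negligible direction modulation",
      sum(r2[sel] < 0.01), n_features))
  H <- t(beta[2:3, sel, drop = FALSE])                # p_sel x 2
  b0 <- beta[1, sel]
  # floor the residual variances so noiseless (exactly linear) features
  # keep the innovation covariance invertible
  qd <- pmax(rss[sel] / (nrow(Z) - 3L),
             1e-6 * max(tss / nrow(Z), 1e-6))
  Q <- diag(qd, length(sel))
  w <- (1 - a^2) * mean(apply(d[, use, drop = FALSE], 1, stats::var))
  A <- a * diag(2)
  W <- w * diag(2)
  # 1e-9 on K is far below any scientific effect; the strict default can
  # limit-cycle in roundoff when Q is floored for noiseless features
  K <- steady_state_gain(A, W, H, Q, tol = 1e-9)
  M1 <- (diag(2) - K %*% H) %*% A
  if (max(abs(eigen(M1, only.values = TRUE)$values)) >= 1)
    stop("decoder recursion unstable: spectral radius of (I - K H) A >= 1")
  structure(
    list(selected_features = sel, baseline = b0, H = H, Q = Q, A = A, W = W,
         K = K, M1 = M1, M2 = K, position_leak = position_leak,
         bin_width = features$bin_width, r2 = r2),
    class = "kalman_model")
}

#' @export
print.kalman_model <- function(x, ...) {
  cat(sprintf(
    "<kalman_model> %d features, a = %.3g, lambda = %.4g, |eig(M1)| = %.4f\n",
    length(x$selected_features), x$A[1, 1], x$position_leak,
    max(abs(eigen(x$M1, only.values = TRUE)$values))))
  invisible(x)
}

#' Decode a feature stream into a hypothetical 2-D cursor trajectory
#'
#' Velocity recursion `v_t = M1 v_{t-1} + M2 (z_t - b)` with `v_0 = 0`;
#' position by leaky integration `p_t = lambda p_{t-1} + dt v_t`, `p_0 = 0`.
#' No rescaling, smoothing or recentering is applied: the output is the raw
#' offline decoder trajectory.
#'
#' @param features a [feature_series()].
#' @param model a `kalman_model` from [calibrate()].
#' @return a [trajectory_series()] on the same bin grid.
#' @export
decode <- function(features, model) {
  stopifnot(inherits(features, "feature_series"),
            inherits(model, "kalman_model"))
  Z <- features$values[model$selected_features, , drop = FALSE]
  bad <- which(!is.finite(colSums(Z)))
  if (length(bad) > 0)
    stop(sprintf("non-finite feature value at bin %d", bad[1]))
  n <- ncol(Z)
  U <- model$M2 %*% (Z - model$baseline)              # 2 x n innovations
  V <- decode_velocity(model$M1, U)
  lam <- model$position_leak
  bw <- model$bin_width
  px <- as.numeric(stats::filter(bw * V[1, ], lam, method = "recursive"))
  py <- as.numeric(stats::filter(bw * V[2, ], lam, method = "recursive"))
  trajectory_series(px, py, V[1, ], V[2, ], bw, features$start_time)
}

# v_t = M1 v_{t-1} + u_t via eigendecomposition of M1 (diagonalizes the
# coupled 2-D recursion into two scalar AR(1) filters, complex-safe);
# falls back to a direct loop for defective M1.
decode_velocity <- function(M1, U) {
  n <- ncol(U)
  eg <- eigen(M1)
  if (abs(det(eg$vectors)) > 1e-10) {
    G <- solve(eg$vectors) %*% U
    Wf <- matrix(0i, 2, n)
    for (k in 1:2) {
      lam <- eg$values[k]
      g <- G[k, ]
      re <- as.numeric(stats::filter(Re(g), Re(lam), method = "recursive"))
      if (abs(Im(lam)) < 1e-14 && all(abs(Im(g)) < 1e-14)) {
        Wf[k, ] <- re
      } else {
        w <- complex(real = 0, imaginary = 0)
        out <- complex(length.out = n)
        for (t in seq_len(n)) {
          w <- lam * w + g[t]
          out[t] <- w
        }
        Wf[k, ] <- out
      }
    }
    V <- Re(eg$vectors %*% Wf)
  } else {
    V <- matrix(0, 2, n)
    v <- c(0, 0)
    for (t in seq_len(n)) {
      v <- as.numeric(M1 %*% v) + U[, t]
      V[, t] <- v
    }
  }
  V
}

#' Serialize / restore a Kalman model as JSON
#'
#' Matrices are stored row-major with explicit dimensions.
#'
#' @param model a `kalman_model`.
#' @param path JSON file path.
#' @return `path` (write) or a `kalman_model` (read).
#' @export
write_kalman_model <- function(model, path) {
  enc <- function(m) list(dim = dim(m), data = as.numeric(t(m)))
  jsonlite::write_json(
    list(selected_features = model$selected_features,
         baseline = model$baseline, H = enc(model$H), Q = enc(model$Q),
         A = enc(model$A), W = enc(model$W), K = enc(model$K),
         position_leak = model$position_leak, bin_width = model$bin_width),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kalman_model
#' @export
read_kalman_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(e) matrix(e$data, e$dim[1], e$dim[2], byrow = TRUE)
  H <- dec(j$H); K <- dec(j$K); A <- dec(j$A)
  M1 <- (diag(2) - K %*% H) %*% A
  structure(
    list(selected_features = j$selected_features, baseline = j$baseline,
         H = H, Q = dec(j$Q), A = A, W = dec(j$W), K = K, M1 = M1, M2 = K,
         position_leak = j$position_leak, bin_width = j$bin_width),
    class = "kalman_model")
}
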