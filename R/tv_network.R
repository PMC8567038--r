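#' Select MVAR model order by AIC
#'
#' Fits stationary MVAR models of each candidate order to every trial by
#' least squares and picks the order minimising the mean AIC across trials,
#' `AIC(p) = log det(Sigma_p) + 2 p n^2 / N` with `Sigma_p` the residual
#' covariance and `N` the number of regression rows.
#'
#' @param epochs an [epoch_array()].
#' @param p_range integer candidate orders, default `1:10`.
#' @return `list(p = selected order, aic = named mean-AIC vector)`.
#' @export
select_model_order <- function(epochs, p_range = 1:10) {
  p_range <- sort(unique(as.integer(p_range)))
  n_samp <- dim(epochs$data)[3L]
  if (max(p_range) >= n_samp - 1L)
    stop(sprintf("max candidate order %d too large for %d-sample trials",
                 max(p_range), n_samp))
  aic <- sapply(p_range, function(p) {
    vals <- vapply(seq_len(n_trials(epochs)), function(tr) {
      X <- t(epochs$data[tr, , ])  # samples x channels
      mvar_aic(X, p)
    }, 0)
    mean(vals)
  })
  names(aic) <- p_range
  if (any(!is.finite(aic))) stop("AIC not finite at some candidate order")
  list(p = p_range[which.min(aic)], aic = aic)
}

# least-squares VAR(p) fit; returns lag matrices and residual covariance
mvar_ls <- function(X, p) {
  N <- nrow(X); n <- ncol(X)
  rows <- (p + 1):N
  Yv <- X[rows, , drop = FALSE]
  Z <- do.call(cbind, lapply(seq_len(p), function(k) X[rows - k, , drop = FALSE]))
  B <- tryCatch(solve(crossprod(Z), crossprod(Z, Yv)),
                error = function(e) qr.solve(Z, Yv))
  resid <- Yv - Z %*% B
  Sigma <- crossprod(resid) / (nrow(Yv) - n * p)
  A <- lapply(seq_len(p), function(k) t(B[(k - 1) * n + seq_len(n), , drop = FALSE]))
  list(A = A, Sigma = Sigma, n_rows = nrow(Yv))
}

mvar_aic <- function(X, p) {
  fit <- mvar_ls(X, p)
  n <- ncol(X)
  det_s <- det(fit$Sigma)
  if (det_s <= 0) det_s <- .Machine$double.eps
  log(det_s) + 2 * p * n^2 / fit$n_rows
}

#' Kalman-filtered time-varying MVAR estimation
#'
#' Tracks the coefficient matrices `A(i, t)` of the time-varying MVAR model
#' `X(t) = sum_i A(i,t) X(t-i) + E(t)` over a single trial with a
#' random-walk-state Kalman filter: the state is the stacked coefficient
#' entries, the state transition is the identity, and process noise is
#' `update_constant` times the identity. Because all channels share the same
#' lagged regressor, one error-covariance recursion serves every channel.
#' The innovation covariance is tracked by exponential smoothing with the
#' same adaptation constant and supplies the observation-noise variance.
#'
#' Initialisation: zero coefficients, unit state covariance, unit innovation
#' covariance.
#'
#' @param trial channels x samples numeric matrix (one epoch).
#' @param p model order (>= 1).
#' @param update_constant Kalman adaptation rate in (0, 1), default 0.02.
#'   Larger values track faster but estimate noisier coefficients.
#' @param fs sampling rate (stored for downstream frequency mapping).
#' @return object of class `tvmvar_model`: `coefficients` is an
#'   n x n x p x T array (target, source, lag, time) defined for every
#'   post-lag sample `t = p+1 .. T`, time points before that hold the
#'   initial (zero) state; plus `innovation_covariance`, `p`,
#'   `update_constant`, `fs`.
#' @export
fit_tvmvar_kalman <- function(trial, p, update_constant = 0.02, fs = NULL) {
  trial <- as.matrix(trial)
  n <- nrow(trial); N <- ncol(trial)
  if (N <= p) stop("trial must have more samples than the model order")
  if (update_constant <= 0 || update_constant >= 1)
    stop("update_constant must lie in (0, 1)")
  uc <- update_constant
  B <- matrix(0, n, n * p)          # current coefficient matrix [A1 .. Ap]
  P <- diag(n * p)                  # shared state covariance
  V <- diag(n)                      # smoothed innovation covariance
  coefs <- array(0, dim = c(n, n, p, N))
  for (tt in (p + 1):N) {
    z <- as.vector(trial[, tt - seq_len(p)])  # stacked lagged observations
    pred <- as.vector(B %*% z)
    err <- trial[, tt] - pred
    P <- P + uc * diag(n * p)                 # random-walk prediction
    r <- mean(diag(V))                        # scalar observation-noise proxy
    Pz <- as.vector(P %*% z)
    s <- sum(z * Pz) + r
    k <- Pz / s                               # shared Kalman gain direction
    B <- B + outer(err, k)
    P <- P - tcrossprod(k, Pz)
    P <- (P + t(P)) / 2                       # keep symmetric
    V <- (1 - uc) * V + uc * tcrossprod(err)
    for (lag in seq_len(p))
      coefs[, , lag, tt] <- B[, (lag - 1) * n + seq_len(n)]
  }
  structure(list(coefficients = coefs, innovation_covariance = V,
                 p = as.integer(p), update_constant = uc, fs = fs,
                 n_channels = n, n_samples = N),
            class = "tvmvar_model")
}

#' @export
print.tvmvar_model <- function(x, ...) {
  cat(sprintf("<tvmvar_model> %d channels, order %d, %d samples, uc = %g\n",
              x$n_channels, x$p, x$n_samples, x$update_constant))
  invisible(x)
}

#' Time-varying frequency-domain transfer function
#'
#' For each retained time point, forms the lag polynomial
#' `A(f, t) = I - sum_{k=1..p} A_k(t) exp(-i 2 pi f k / fs)` (the identity is
#' the lag-0 term) and inverts it: `H(f, t) = A(f, t)^{-1}`. `|H_ij(f, t)|`
#' measures the flow of information from node j to node i at frequency f and
#' time t. A numerically singular `A(f, t)` falls back to the Moore-Penrose
#' pseudo-inverse with a warning.
#'
#' @param model a [fit_tvmvar_kalman()] result (with `fs` set).
#' @param freqs frequencies in Hz, all below `fs / 2`.
#' @param time_points sample indices at which to evaluate; default all
#'   post-lag samples `p+1 .. T`.
#' @return object of class `transfer_tensor`: complex array `H` of dimension
#'   n x n x length(freqs) x length(time_points), plus the grids.
#' @export
transfer_function <- function(model, freqs, time_points = NULL) {
  stopifnot(inherits(model, "tvmvar_model"))
  fs <- model$fs
  if (is.null(fs)) stop("model carries no sampling rate")
  if (any(freqs >= fs / 2)) stop("frequencies must be below fs/2")
  n <- model$n_channels; p <- model$p
  if (is.null(time_points)) time_points <- (p + 1):model$n_samples
  H <- array(complex(real = 0), dim = c(n, n, length(freqs), length(time_points)))
  I_n <- diag(n)
  sing <- 0L
  for (ti in seq_along(time_points)) {
    tt <- time_points[ti]
    Ak <- lapply(seq_len(p), function(k) model$coefficients[, , k, tt])
    for (fi in seq_along(freqs)) {
      Af <- I_n + 0i
      for (k in seq_len(p))
        Af <- Af - Ak[[k]] * exp(-2i * pi * freqs[fi] * k / fs)
      Hf <- tryCatch(solve(Af), error = function(e) NULL)
      if (is.null(Hf)) {
        sing <- sing + 1L
        sv <- svd(Af)
        pos <- sv$d > max(sv$d) * 1e-12
        Hf <- sv$v[, pos, drop = FALSE] %*%
          ((1 / sv$d[pos]) * Conj(t(sv$u[, pos, drop = FALSE])))
      }
      H[, , fi, ti] <- Hf
    }
  }
  if (sing > 0L)
    warning(sprintf("%d singular A(f, t) matrices replaced by pseudo-inverse", sing))
  structure(list(H = H, freqs = freqs, time_points = time_points,
                 fs = fs, n_channels = n),
            class = "transfer_tensor")
}

#' Normalized adaptive directed transfer function (ADTF)
#'
#' Per target channel i, frequency f and time t, normalises the squared
#' transfer-function magnitudes over sources:
#' `gamma2_ij(f, t) = |H_ij(f, t)|^2 / sum_m |H_im(f, t)|^2`, so each entry
#' lies in [0, 1] and each target's source-sum is exactly 1. An all-zero row
#' (degenerate transfer function) maps to zeros and is flagged.
#'
#' @param tf a [transfer_function()] result.
#' @return object of class `adtf_tensor`: real array `gamma2` of dimension
#'   target x source x frequency x time, plus the grids and a
#'   `degenerate_rows` count.
#' @export
adtf <- function(tf) {
  stopifnot(inherits(tf, "transfer_tensor"))
  H2 <- Mod(tf$H)^2
  d <- dim(H2)
  gamma2 <- H2
  degenerate <- 0L
  for (ti in seq_len(d[4])) for (fi in seq_len(d[3])) {
    slab <- H2[, , fi, ti, drop = FALSE]
    dim(slab) <- d[1:2]
    rs <- rowSums(slab)
    zero <- rs == 0
    if (any(zero)) { degenerate <- degenerate + sum(zero); rs[zero] <- 1 }
    gamma2[, , fi, ti] <- slab / rs
  }
  structure(list(gamma2 = gamma2, freqs = tf$freqs,
                 time_points = tf$time_points, fs = tf$fs,
                 degenerate_rows = degenerate),
            class = "adtf_tensor")
}

#' Band-integrated ADTF network
#'
#' Averages the ADTF over the grid frequencies inside the band `[f1, f2]`
#' (inclusive), yielding the time-resolved integrated network
#' `Theta2_ij(t)`. Because each frequency slice is row-normalised, the
#' integrated network inherits per-target row sums of 1.
#'
#' @param adtf_tensor an [adtf()] result.
#' @param band `c(f1, f2)` in Hz; must contain at least one grid frequency.
#'   Default `c(1, 10)`, the delta-through-alpha band carrying the P300.
#' @return object of class `integrated_network`: array `theta2` of dimension
#'   target x source x time, the band, time grid and fs.
#' @export
integrate_adtf <- function(adtf_tensor, band = c(1, 10)) {
  stopifnot(inherits(adtf_tensor, "adtf_tensor"))
  sel <- which(adtf_tensor$freqs >= band[1] & adtf_tensor$freqs <= band[2])
  if (!length(sel)) stop("no grid frequencies inside the band")
  g <- adtf_tensor$gamma2[, , sel, , drop = FALSE]
  theta2 <- apply(g, c(1, 2, 4), mean)
  structure(list(theta2 = theta2, band = as.numeric(band),
                 freqs_used = adtf_tensor$freqs[sel],
                 time_points = adtf_tensor$time_points, fs = adtf_tensor$fs),
            class = "integrated_network")
}

#' Average integrated networks across trials
#'
#' Elementwise mean of per-trial integrated networks, optionally split by a
#' condition label vector. All networks must share the time grid and band.
#'
#' @param networks list of [integrate_adtf()] results (one per trial).
#' @param by optional per-trial condition labels; if `NULL` a single average
#'   is returned.
#' @return a single `integrated_network`, or a named list of them (one per
#'   condition).
#' @export
average_networks <- function(networks, by = NULL) {
  stopifnot(length(networks) >= 1L)
  ref <- networks[[1L]]
  for (nw in networks) {
    if (!identical(dim(nw$theta2), dim(ref$theta2)) ||
        !identical(nw$time_points, ref$time_points) ||
        !identical(nw$band, ref$band))
      stop("networks have mismatched grids or bands")
  }
  avg <- function(idx) {
    th <- Reduce(`+`, lapply(networks[idx], `[[`, "theta2")) / length(idx)
    structure(list(theta2 = th, band = ref$band, freqs_used = ref$freqs_used,
                   time_points = ref$time_points, fs = ref$fs,
                   n_trials = length(idx)),
              class = "integrated_network")
  }
  if (is.null(by)) return(avg(seq_along(networks)))
  if (length(by) != length(networks))
    stop("`by` must have one label per network")
  conds <- unique(by)
  out <- lapply(conds, function(cond) avg(which(by == cond)))
  names(out) <- conds
  out
}

#' Substage source-node summary
#'
#' For each named substage (ms interval on the epoch time axis), sums the
#' off-diagonal outgoing integrated-ADTF weights of every node over the
#' substage's time points: `outflow(j) = sum_{i != j, t in stage}
#' Theta2_ij(t)`. The node with maximal outflow is reported as the stage's
#' source region (ties flagged), together with the `top_k` strongest directed
#' edges (summed over the stage).
#'
#' @param network an [integrate_adtf()] / [average_networks()] result.
#' @param stages named list of ms intervals, default the decision-process
#'   (200-320 ms) and neuronal-response (320-440 ms) substages.
#' @param channel_labels node names (length = network dimension).
#' @param epoch_window epoch window in ms used to place the time grid,
#'   default `c(-200, 800)`.
#' @param top_k number of edges to list per stage, default 10.
#' @return object of class `network_summary`: per-stage list with `outflow`
#'   (named vector), `source`, `tie` flag and an `edges` data.frame.
#' @export
summarize_substages <- function(network, stages = default_substages(),
                                channel_labels = NULL,
                                epoch_window = c(-200, 800), top_k = 10) {
  stopifnot(inherits(network, "integrated_network"))
  n <- dim(network$theta2)[1L]
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(n))
  if (length(channel_labels) != n) stop("channel label count mismatch")
  fs <- network$fs
  t_ms <- epoch_window[1] + (network$time_points - 1) * 1000 / fs
  res <- lapply(names(stages), function(st) {
    iv <- stages[[st]]
    sel <- which(t_ms >= iv[1] & t_ms < iv[2])
    if (!length(sel))
      stop(sprintf("substage %s [%g, %g) ms contains no time points", st, iv[1], iv[2]))
    Th <- network$theta2[, , sel, drop = FALSE]
    W <- apply(Th, c(1, 2), sum)            # target x source, summed over stage
    diag(W) <- 0
    outflow <- colSums(W)
    names(outflow) <- channel_labels
    top <- which(outflow == max(outflow))
    edges <- data.frame(
      source = channel_labels[as.vector(col(W))],
      target = channel_labels[as.vector(row(W))],
      weight = as.vector(W), stringsAsFactors = FALSE)
    edges <- edges[edges$source != edges$target, ]
    edges <- edges[order(-edges$weight), ]
    k <- min(top_k, nrow(edges))
    list(stage = st, interval_ms = iv, outflow = outflow,
         source = channel_labels[top[1L]], tie = length(top) > 1L,
         n_time_points = length(sel),
         edges = utils::head(edges, k))
  })
  names(res) <- names(stages)
  structure(res, class = "network_summary")
}

#' Default decision substages
#'
#' The decision-process (200-320 ms) and neuronal-response (320-440 ms)
#' windows bracketing the P3 peak.
#'
#' @return named list of ms intervals.
#' @export
default_substages <- function() {
  list(decision_process = c(200, 320), neuronal_response = c(320, 440))
}

#' @export
print.network_summary <- function(x, ...) {
  cat("<network_summary>\n")
  for (st in x) {
    cat(sprintf("  %s [%g, %g) ms: source = %s%s (outflow %.3f over %d points)\n",
                st$stage, st$interval_ms[1], st$interval_ms[2], st$source,
                if (st$tie) " (tie)" else "", max(st$outflow), st$n_time_points))
  }
  invisible(x)
}

#' Per-trial ADTF network pipeline
#'
#' Convenience wrapper running, for every trial of an epoch array: Kalman
#' tv-MVAAR fit, transfer function on the frequency grid, ADTF normalisation
#' and band integration; then averages the per-trial integrated networks by
#' condition (per the estimate-then-average order).
#'
#' @param epochs an [epoch_array()] (already downsampled to the network rate).
#' @param p model order; `NULL` selects it by AIC over `p_range`.
#' @param p_range AIC candidates when `p` is `NULL`.
#' @param update_constant Kalman adaptation rate.
#' @param freqs frequency grid in Hz, default `1:10` (1 Hz steps over the
#'   1-10 Hz band at the 25 Hz network rate).
#' @param band integration band, default `c(1, 10)`.
#' @return `list(networks = per-condition (or pooled) integrated networks,
#'   p =, aic =)`.
#' @export
trial_networks <- function(epochs, p = NULL, p_range = 1:5,
                           update_constant = 0.02, freqs = 1:10,
                           band = c(1, 10)) {
  aic <- NULL
  if (is.null(p)) {
    sel <- select_model_order(epochs, p_range)
    p <- sel$p; aic <- sel$aic
  }
  nets <- lapply(seq_len(n_trials(epochs)), function(tr) {
    model <- fit_tvmvar_kalman(epochs$data[tr, , ], p,
                               update_constant = update_constant, fs = epochs$fs)
    integrate_adtf(adtf(transfer_function(model, freqs)), band)
  })
  networks <- average_networks(nets, by = epochs$condition_labels)
  list(networks = networks, p = p, aic = aic)
}

#' Classical (stationary) directed transfer function
#'
#' DTF of a fixed-coefficient MVAR model: the time-invariant analogue of the
#' ADTF, used as an independent reference on stationary data. Accepts lag
#' matrices directly, so it can be evaluated on the true generating
#' coefficients of a simulation.
#'
#' @param A list of p lag matrices (or a single matrix for p = 1).
#' @param freqs frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @return target x source x frequency array of normalized squared DTF values.
#' @export
classical_dtf <- function(A, freqs, fs) {
  if (is.matrix(A)) A <- list(A)
  n <- nrow(A[[1L]])
  out <- array(0, dim = c(n, n, length(freqs)))
  for (fi in seq_along(freqs)) {
    Af <- diag(n) + 0i
    for (k in seq_along(A))
      Af <- Af - A[[k]] * exp(-2i * pi * freqs[fi] * k / fs)
    H2 <- Mod(solve(Af))^2
    out[, , fi] <- H2 / rowSums(H2)
  }
  out
}
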