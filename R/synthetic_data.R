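#' Ground-truth coefficient schedule for a time-varying MVAR process
#'
#' A `coefficient_schedule` defines a piecewise-constant time-varying
#' multivariate autoregressive (MVAR) generative model: within each time
#' segment the process follows `X(t) = sum_i A_i X(t-i) + E(t)` with fixed
#' coefficient matrices; at segment boundaries the coefficients switch
#' instantaneously. Segments are half-open ms intervals `[start, end)` and
#' must tile the simulated epoch window without gaps or overlap.
#'
#' @param order model order `p` (number of lags).
#' @param segments list of segments, each `list(interval = c(start_ms, end_ms),
#'   A = list of p channel x channel matrices)` (lag 1 first).
#' @param noise_covariance channel x channel symmetric positive-definite
#'   innovation covariance (uV^2).
#'
#' @return An object of class `coefficient_schedule`.
#' @export
coefficient_schedule <- function(order, segments, noise_covariance) {
  order <- as.integer(order)
  if (order < 1L) stop("`order` must be >= 1")
  if (!length(segments)) stop("at least one segment is required")
  n <- nrow(noise_covariance)
  if (!isTRUE(all.equal(noise_covariance, t(noise_covariance), tolerance = 1e-10)))
    stop("noise covariance must be symmetric")
  ev <- eigen(noise_covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("noise covariance must be positive-definite")
  segments <- lapply(segments, function(s) {
    if (is.null(s$interval) || length(s$interval) != 2L || s$interval[2] <= s$interval[1])
      stop("each segment needs interval = c(start_ms, end_ms), end > start")
    A <- s$A
    if (is.matrix(A)) A <- list(A)
    if (length(A) != order)
      stop(sprintf("segment must supply %d lag matrices (got %d)", order, length(A)))
    for (Ak in A) {
      if (!is.matrix(Ak) || any(dim(Ak) != n))
        stop("every lag matrix must be channel x channel and match the noise covariance")
    }
    rho <- companion_spectral_radius(A)
    if (rho >= 1)
      stop(sprintf("unstable segment [%g, %g) ms: companion spectral radius %.3f >= 1",
                   s$interval[1], s$interval[2], rho))
    list(interval = as.numeric(s$interval), A = lapply(A, function(m) {
      storage.mode(m) <- "double"; m
    }))
  })
  starts <- vapply(segments, function(s) s$interval[1], 0)
  segments <- segments[order(starts)]
  for (k in seq_along(segments)[-1]) {
    if (!isTRUE(all.equal(segments[[k]]$interval[1], segments[[k - 1]]$interval[2])))
      stop("segment intervals must tile contiguously without overlap")
  }
  structure(list(order = order, segments = segments,
                 noise_covariance = noise_covariance, n_channels = n),
            class = "coefficient_schedule")
}

#' Spectral radius of the MVAR companion matrix
#'
#' A VAR(p) with lag matrices `A_1..A_p` is stable iff the companion matrix
#' `[A_1 .. A_p; I 0]` has spectral radius < 1.
#'
#' @param A list of p square lag matrices.
#' @return largest eigenvalue modulus of the companion matrix.
#' @export
companion_spectral_radius <- function(A) {
  if (is.matrix(A)) A <- list(A)
  n <- nrow(A[[1L]]); p <- length(A)
  C <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) C[seq_len(n), (k - 1L) * n + seq_len(n)] <- A[[k]]
  if (p > 1L)
    C[n + seq_len(n * (p - 1L)), seq_len(n * (p - 1L))] <-
      diag(n * (p - 1L))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

# deterministic per-trial substream: trial k of a run seeded with `seed`
# always sees the same RNG state regardless of total trial count
trial_seed <- function(seed, trial) {
  (as.integer(seed) %% 1000003L) * 2048L + as.integer(trial) %% 2048L
}

#' Simulate epochs from a time-varying MVAR process
#'
#' Draws independent trials from the piecewise-constant time-varying MVAR
#' model in `schedule`. Each trial starts from a burn-in of `10 * p` samples
#' generated under the first segment's coefficients (discarded), so the
#' retained epoch window carries no initial-condition transient. A fixed seed
#' gives bit-identical output; trials use per-trial substreams so increasing
#' `n_trials` never reshuffles earlier trials.
#'
#' @param schedule a [coefficient_schedule()]; segments must tile `window`.
#' @param n_trials number of trials (>= 1).
#' @param n_channels number of channels; must match the schedule.
#' @param fs sampling rate in Hz.
#' @param window epoch window in ms, half-open `[start, end)`.
#' @param seed integer seed.
#' @param channel_labels optional labels (defaults to `"ch1"..`).
#' @param condition optional single condition label attached to all trials.
#'
#' @return an [epoch_array()] with attribute `"schedule"` carrying the ground truth.
#' @export
simulate_tvmvar <- function(schedule, n_trials, n_channels, fs, window, seed,
                            channel_labels = NULL, condition = NULL) {
  stopifnot(inherits(schedule, "coefficient_schedule"))
  if (n_channels != schedule$n_channels)
    stop("`n_channels` must match the schedule's matrices")
  if (n_trials < 1L) stop("`n_trials` must be >= 1")
  if (fs <= 0) stop("`fs` must be positive")
  span <- range(unlist(lapply(schedule$segments, `[[`, "interval")))
  if (!isTRUE(all.equal(span, as.numeric(window))))
    stop(sprintf("schedule segments tile [%g, %g) ms but window is [%g, %g) ms",
                 span[1], span[2], window[1], window[2]))
  p <- schedule$order
  n_samples <- round((window[2] - window[1]) * fs / 1000)
  burn <- 10L * p
  L <- chol(schedule$noise_covariance)
  # per-sample segment index for the retained window
  t_ms <- window[1] + (seq_len(n_samples) - 1) * 1000 / fs
  seg_of <- vapply(t_ms, function(tt) {
    for (k in seq_along(schedule$segments)) {
      iv <- schedule$segments[[k]]$interval
      if (tt >= iv[1] && tt < iv[2]) return(k)
    }
    stop("internal: sample time outside schedule")
  }, 0L)
  data <- array(0, dim = c(n_trials, n_channels, n_samples))
  total <- burn + n_samples
  for (tr in seq_len(n_trials)) {
    set.seed(trial_seed(seed, tr))
    E <- t(matrix(stats::rnorm(total * n_channels), n_channels, total))
    E <- E %*% L  # rows: time, cols: channels
    X <- matrix(0, total, n_channels)
    for (tt in seq_len(total)) {
      seg <- if (tt <= burn) 1L else seg_of[tt - burn]
      A <- schedule$segments[[seg]]$A
      x <- E[tt, ]
      for (k in seq_len(p)) {
        if (tt - k >= 1L) x <- x + as.vector(A[[k]] %*% X[tt - k, ])
      }
      X[tt, ] <- x
    }
    data[tr, , ] <- t(X[burn + seq_len(n_samples), , drop = FALSE])
  }
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(n_channels))
  out <- epoch_array(data, fs, window, channel_labels,
                     condition_labels = if (!is.null(condition)) rep(condition, n_trials))
  attr(out, "schedule") <- schedule
  out
}

#' ERP template set
#'
#' Per-condition noise-free ERP waveforms built from Gaussian component bumps
#' (P2, P3, LPC by default) over electrode clusters, plus the trial noise SD
#' used by [make_erp_epochs()]. Cluster electrodes receive the full component
#' amplitude; remaining scalp channels receive `spread` times it, mimicking the
#' broad spatial falloff of real components without a forward model.
#'
#' @param channel_labels montage (default [montage_32()]).
#' @param fs sampling rate (Hz), default 500.
#' @param window epoch window ms, default `c(-200, 800)`.
#' @param components list of component definitions: each
#'   `list(name, center_ms, sd_ms, electrodes, amplitude = c(LAI =, HAI =))`.
#'   Defaults follow the conventional P2 / P3 / LPC windows and clusters, with
#'   a smaller P2 and P3 but larger LPC under the high-information condition.
#' @param noise_sd trial noise standard deviation in uV (>= 0), default 10.
#' @param spread off-cluster amplitude fraction, default 0.3.
#'
#' @return object of class `erp_template_set` with per-condition
#'   channels x samples waveform matrices.
#' @export
erp_template_set <- function(channel_labels = montage_32(), fs = 500,
                             window = c(-200, 800),
                             components = default_erp_components(),
                             noise_sd = 10, spread = 0.3) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  n_samples <- round((window[2] - window[1]) * fs / 1000)
  t_ms <- window[1] + (seq_len(n_samples) - 1) * 1000 / fs
  conds <- unique(unlist(lapply(components, function(cp) names(cp$amplitude))))
  waves <- lapply(conds, function(cond) {
    W <- matrix(0, length(channel_labels), n_samples,
                dimnames = list(channel_labels, NULL))
    for (cp in components) {
      missing <- setdiff(cp$electrodes, channel_labels)
      if (length(missing))
        stop("component ", cp$name, " references unknown electrode(s): ",
             paste(missing, collapse = ", "))
      amp <- cp$amplitude[[cond]]
      bump <- amp * exp(-0.5 * ((t_ms - cp$center_ms) / cp$sd_ms)^2)
      w <- ifelse(channel_labels %in% cp$electrodes, 1, spread)
      W <- W + outer(w, bump)
    }
    W
  })
  names(waves) <- conds
  structure(list(waveforms = waves, fs = fs, window = as.numeric(window),
                 channel_labels = channel_labels, components = components,
                 noise_sd = noise_sd),
            class = "erp_template_set")
}

#' Default ERP component definitions
#'
#' P2 (140-200 ms, fronto-central cluster), P3 (300-400 ms, centro-parietal
#' cluster) and LPC (500-700 ms, fronto-central cluster), with low- (LAI) vs
#' high-amount-of-information (HAI) amplitudes: P2 2.034 vs 1.606 uV, P3 5 vs
#' 3.5 uV, LPC 3 vs 4.2 uV (LAI > HAI for P2/P3; HAI > LAI for LPC).
#'
#' @return list of component definitions for [erp_template_set()].
#' @export
default_erp_components <- function() {
  fc <- c("F3", "F4", "FC1", "FC2", "Fz", "C3", "C4", "Cz")
  cp <- c("C3", "C4", "CP1", "CP2", "Cz", "P3", "P4", "Pz")
  list(
    list(name = "P2", center_ms = 170, sd_ms = 15, electrodes = fc,
         amplitude = c(LAI = 2.034, HAI = 1.606)),
    list(name = "P3", center_ms = 350, sd_ms = 35, electrodes = cp,
         amplitude = c(LAI = 5.0, HAI = 3.5)),
    list(name = "LPC", center_ms = 600, sd_ms = 60, electrodes = fc,
         amplitude = c(LAI = 3.0, HAI = 4.2))
  )
}

#' Generate ERP-like epochs from templates
#'
#' Each epoch equals its condition template plus independent Gaussian noise of
#' the template set's `noise_sd`, so grand averages converge to the templates
#' at rate 1/sqrt(n).
#'
#' @param templates an [erp_template_set()].
#' @param n_trials_per_condition trials per condition (>= 1).
#' @param seed integer seed.
#' @param n_participants number of participants the trials are split across
#'   (round-robin within condition, so every participant sees both
#'   conditions); `NULL` (default) attaches no participant ids.
#' @return an [epoch_array()] with condition labels attached.
#' @export
make_erp_epochs <- function(templates, n_trials_per_condition, seed,
                            n_participants = NULL) {
  stopifnot(inherits(templates, "erp_template_set"))
  if (n_trials_per_condition < 1L) stop("need n >= 1 trials per condition")
  conds <- names(templates$waveforms)
  n_ch <- length(templates$channel_labels)
  n_sm <- ncol(templates$waveforms[[1L]])
  n_tot <- n_trials_per_condition * length(conds)
  data <- array(0, dim = c(n_tot, n_ch, n_sm))
  labels <- character(n_tot)
  pids <- character(n_tot)
  tr <- 0L
  for (ci in seq_along(conds)) {
    W <- templates$waveforms[[ci]]
    for (k in seq_len(n_trials_per_condition)) {
      tr <- tr + 1L
      set.seed(trial_seed(seed + 7919L * (ci - 1L), k))
      data[tr, , ] <- W + matrix(stats::rnorm(n_ch * n_sm, sd = templates$noise_sd),
                                 n_ch, n_sm)
      labels[tr] <- conds[ci]
      if (!is.null(n_participants))
        pids[tr] <- sprintf("p%03d", (k - 1L) %% n_participants + 1L)
    }
  }
  epoch_array(data, templates$fs, templates$window, templates$channel_labels,
              condition_labels = labels,
              participant_ids = if (!is.null(n_participants)) pids)
}

#' Simulate behavioural response times
#'
#' Draws per-trial response times from condition-specific log-normal
#' distributions and censors at the 4,000 ms response deadline: censored
#' trials are flagged as non-responses (`responded = FALSE`, `rt_ms = NA`).
#' Defaults reproduce the study conditions (low- vs high-information
#' two-alternative purchase decisions): location/scale chosen so that the
#' analytic median and mean match 950/1106.68 ms (LAI) and 1390/1511.69 ms
#' (HAI).
#'
#' @param n_trials trials per condition.
#' @param lai_params,hai_params `list(location =, scale =)` of the log-normal
#'   (scale >= 0).
#' @param seed integer seed.
#' @param deadline_ms response deadline, default 4000.
#' @return a `data.frame` with columns `trial_id`, `condition`, `rt_ms`,
#'   `responded`; trials are paired across conditions by `trial_id`.
#' @export
simulate_behavior <- function(n_trials,
                              lai_params = list(location = log(950),  scale = 0.5526265),
                              hai_params = list(location = log(1390), scale = 0.4096961),
                              seed = 1L, deadline_ms = 4000) {
  for (p in list(lai_params, hai_params))
    if (is.null(p$location) || is.null(p$scale) || p$scale < 0)
      stop("params must supply location and scale >= 0")
  rows <- list()
  params <- list(LAI = lai_params, HAI = hai_params)
  for (ci in seq_along(params)) {
    set.seed(trial_seed(seed + 104729L * (ci - 1L), 0L))
    rt <- exp(params[[ci]]$location + params[[ci]]$scale * stats::rnorm(n_trials))
    responded <- rt <= deadline_ms
    rows[[ci]] <- data.frame(
      trial_id = seq_len(n_trials),
      condition = names(params)[ci],
      rt_ms = ifelse(responded, rt, NA_real_),
      responded = responded,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write epochs as delimited per-trial matrices plus a JSON sidecar
#'
#' One tab-separated file per trial (`trial_0001.tsv`, ...), samples as rows
#' and channels as columns with a header row of channel labels, plus
#' `epochs.json` recording fs, window, condition labels and (if present) the
#' ground-truth coefficient schedule.
#'
#' @param epochs an [epoch_array()].
#' @param dir output directory (created if needed).
#' @return invisibly, the sidecar path.
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nt <- n_trials(epochs)
  files <- sprintf("trial_%04d.tsv", seq_len(nt))
  for (tr in seq_len(nt)) {
    m <- t(epochs$data[tr, , ])
    colnames(m) <- epochs$channel_labels
    utils::write.table(m, file.path(dir, files[tr]), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  sidecar <- list(fs = epochs$fs, window = epochs$window,
                  channel_labels = epochs$channel_labels,
                  condition_labels = epochs$condition_labels,
                  participant_ids = epochs$participant_ids,
                  trial_files = files)
  sch <- attr(epochs, "schedule")
  if (!is.null(sch))
    sidecar$schedule <- list(
      order = sch$order,
      segments = lapply(sch$segments, function(s)
        list(interval = s$interval, A = lapply(s$A, function(m) unclass(m)))),
      noise_covariance = unclass(sch$noise_covariance))
  path <- file.path(dir, "epochs.json")
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read epochs written by [write_epochs()]
#'
#' @param dir directory holding `epochs.json` and the per-trial matrices.
#' @return an [epoch_array()].
#' @export
read_epochs <- function(dir) {
  path <- file.path(dir, "epochs.json")
  if (!file.exists(path)) stop("no epochs.json sidecar in ", dir)
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels <- meta$channel_labels
  nt <- length(meta$trial_files)
  first <- as.matrix(utils::read.table(file.path(dir, meta$trial_files[1]),
                                       header = TRUE, sep = "\t", check.names = FALSE))
  data <- array(0, dim = c(nt, length(labels), nrow(first)))
  for (tr in seq_len(nt)) {
    m <- as.matrix(utils::read.table(file.path(dir, meta$trial_files[tr]),
                                     header = TRUE, sep = "\t", check.names = FALSE))
    if (!identical(colnames(m), as.character(labels)))
      stop("channel labels in ", meta$trial_files[tr], " do not match the sidecar")
    data[tr, , ] <- t(m)
  }
  epoch_array(data, meta$fs, meta$window, labels,
              condition_labels = meta$condition_labels,
              participant_ids = meta$participant_ids)
}

#' Write / read a behavioural table
#'
#' Tab-separated text with columns `trial_id`, `condition`, `rt_ms`,
#' `responded`.
#'
#' @param behavior data.frame as returned by [simulate_behavior()].
#' @param path file path.
#' @return `write_behavior` invisibly returns `path`; `read_behavior` the table.
#' @export
write_behavior <- function(behavior, path) {
  utils::write.table(behavior, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
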