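#' Zero-phase band-pass filter
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass to every
#' channel of every trial. The band is realised as a cascade of a 2nd-order
#' high-pass and a 4th-order low-pass; forward-backward filtering doubles the
#' effective order and cancels phase delay, so component latencies are not
#' shifted. Because an ERP high-pass corner (0.1 Hz) lies far below the
#' length of a 1-s epoch, a recursive transient would dominate the output;
#' the 0 Hz component is therefore removed exactly (per-channel demeaning)
#' before the recursive high-pass is applied.
#'
#' @param epochs an [epoch_array()].
#' @param low,high band edges in Hz; `0 < low < high < fs/2`.
#' @return a filtered [epoch_array()] of identical shape.
#' @export
bandpass_filter <- function(epochs, low, high) {
  fs <- epochs$fs
  if (!(low > 0 && low < high && high < fs / 2))
    stop(sprintf("band [%g, %g] Hz must satisfy 0 < low < high < fs/2 = %g",
                 low, high, fs / 2))
  hp <- signal::butter(2, low / (fs / 2), type = "high")
  lp <- signal::butter(4, high / (fs / 2), type = "low")
  out <- epochs$data
  d <- dim(out)
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      x <- out[tr, ch, ]
      x <- x - mean(x)            # exact removal of the 0 Hz component
      x <- signal::filtfilt(hp, x)
      x <- signal::filtfilt(lp, x)
      out[tr, ch, ] <- x
    }
  }
  epoch_array(out, fs, epochs$window, epochs$channel_labels,
              epochs$condition_labels, epochs$participant_ids)
}

#' Segment a continuous recording into stimulus-locked epochs
#'
#' Cuts one epoch per event marker, with the marker sample anchored at 0 ms.
#' Under the half-open convention, a window `[a, b)` ms takes sample offsets
#' `floor(a*fs/1000) .. floor(b*fs/1000) - 1` relative to the marker. Markers
#' too close to a recording edge for the full window are skipped with a
#' warning; zero markers yield an empty (0-trial) array.
#'
#' @param continuous channels x samples numeric matrix (rows may be named).
#' @param markers 1-based sample indices of stimulus onsets.
#' @param window epoch window in ms, e.g. `c(-200, 800)`.
#' @param fs sampling rate in Hz.
#' @param channel_labels channel names; default taken from `rownames(continuous)`.
#' @param condition_labels optional per-marker condition labels.
#' @return an [epoch_array()].
#' @export
segment_epochs <- function(continuous, markers, window, fs,
                           channel_labels = rownames(continuous),
                           condition_labels = NULL) {
  continuous <- as.matrix(continuous)
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(continuous)))
  off_from <- floor(window[1] * fs / 1000)
  off_to   <- floor(window[2] * fs / 1000) - 1L  # inclusive
  n_samp <- off_to - off_from + 1L
  keep <- logical(length(markers))
  for (i in seq_along(markers)) {
    lo <- markers[i] + off_from
    hi <- markers[i] + off_to
    keep[i] <- lo >= 1L && hi <= ncol(continuous)
    if (!keep[i])
      warning(sprintf("marker at sample %d too close to recording edge; trial skipped",
                      markers[i]))
  }
  markers_kept <- markers[keep]
  data <- array(0, dim = c(length(markers_kept), nrow(continuous), n_samp))
  for (i in seq_along(markers_kept))
    data[i, , ] <- continuous[, markers_kept[i] + off_from:off_to, drop = FALSE]
  epoch_array(data, fs, window, channel_labels,
              condition_labels = if (!is.null(condition_labels)) condition_labels[keep])
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline interval, so
#' post-stimulus deflections are measured from a zero pre-stimulus level.
#'
#' @param epochs an [epoch_array()].
#' @param baseline ms interval within the epoch window, default `c(-200, 0)`.
#' @return a baseline-corrected [epoch_array()].
#' @export
baseline_correct <- function(epochs, baseline = c(-200, 0)) {
  idx <- ms_to_samples(epochs, baseline)
  out <- epochs$data
  d <- dim(out)
  if (d[1] > 0) {
    base_mean <- apply(out[, , idx, drop = FALSE], c(1, 2), mean)
    out <- out - array(base_mean, dim = d)  # recycles over samples
  }
  epoch_array(out, epochs$fs, epochs$window, epochs$channel_labels,
              epochs$condition_labels, epochs$participant_ids)
}

#' Reject high-amplitude artifact trials
#'
#' Removes every trial whose peak absolute amplitude on any channel strictly
#' exceeds `threshold` (a trial peaking exactly at the threshold is kept).
#'
#' @param epochs an [epoch_array()] (normally baseline-corrected).
#' @param threshold rejection threshold in uV, default 75 (i.e. +/-75 uV).
#' @return `list(epochs =, report =)` where `report` is a `rejection_report`
#'   with kept/rejected indices and per-trial peaks.
#' @export
reject_artifacts <- function(epochs, threshold = 75) {
  if (threshold <= 0) stop("`threshold` must be positive")
  nt <- n_trials(epochs)
  peaks <- vapply(seq_len(nt), function(tr) max(abs(epochs$data[tr, , ])), 0)
  rejected <- which(peaks > threshold)
  kept <- setdiff(seq_len(nt), rejected)
  if (!length(kept))
    stop(sprintf("all %d trials exceed the +/-%g uV artifact threshold", nt, threshold))
  report <- structure(
    list(kept = kept, rejected = rejected, peak_uv = peaks, threshold = threshold),
    class = "rejection_report")
  list(epochs = subset_trials(epochs, kept), report = report)
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf("<rejection_report> threshold +/-%g uV: %d kept, %d rejected\n",
              x$threshold, length(x$kept), length(x$rejected)))
  invisible(x)
}

#' Anti-aliased integer decimation
#'
#' Decimates each channel by the integer factor `fs / target_fs`, low-pass
#' filtering first (zero-phase 6th-order Butterworth, cutoff at 0.8 of each
#' stage's new Nyquist). Large factors are decomposed into stages of at most
#' 5, which keeps the recursive filters far from their numerical stability
#' limit (a single-stage design at factor 20 would need a cutoff of 0.04 of
#' Nyquist, where high-order IIR coefficients degenerate). At 500 -> 25 Hz
#' this yields one sample every 40 ms.
#'
#' @param epochs an [epoch_array()].
#' @param target_fs target rate in Hz; `fs` must be an integer multiple.
#' @return an [epoch_array()] at `target_fs`.
#' @export
downsample <- function(epochs, target_fs) {
  fs <- epochs$fs
  q <- fs / target_fs
  if (abs(q - round(q)) > 1e-9)
    stop(sprintf("fs = %g Hz is not an integer multiple of target %g Hz", fs, target_fs))
  q <- as.integer(round(q))
  if (q == 1L) return(epochs)
  stages <- integer()
  rem <- q
  for (f in c(5L, 4L, 3L, 2L)) while (rem %% f == 0L) { stages <- c(stages, f); rem <- rem %/% f }
  if (rem != 1L) stages <- c(stages, rem)  # residual prime factor > 5
  d <- dim(epochs$data)
  # demean + odd-reflection padding keeps the zero-phase low-pass free of
  # end transients (short filter memory, so reflection is safe here)
  dec1 <- function(x, qi) {
    lp <- signal::butter(6, 0.8 / qi, type = "low")
    n <- length(x); m <- mean(x); x <- x - m
    L <- min(3L * qi + 18L, n - 1L)
    xp <- c(2 * x[1] - rev(x[2:(L + 1)]), x, 2 * x[n] - rev(x[(n - L):(n - 1)]))
    y <- signal::filtfilt(lp, xp)[L + seq_len(n)] + m
    y[seq.int(1L, n, by = qi)]
  }
  n_new <- d[3]
  for (qi in stages) n_new <- length(seq.int(1L, n_new, by = qi))
  out <- array(0, dim = c(d[1], d[2], n_new))
  for (tr in seq_len(d[1]))
    for (ch in seq_len(d[2])) {
      x <- epochs$data[tr, ch, ]
      for (qi in stages) x <- dec1(x, qi)
      out[tr, ch, ] <- x
    }
  epoch_array(out, target_fs, epochs$window, epochs$channel_labels,
              epochs$condition_labels, epochs$participant_ids)
}

#' Re-reference epochs
#'
#' Subtracts a reference signal from every channel: the grand mean across all
#' channels (`scheme = "average"`) or the mean of a named channel list (e.g.
#' the mastoid pair `c("TP9", "TP10")` for a linked-mastoid reference).
#'
#' @param epochs an [epoch_array()].
#' @param scheme `"average"` or a character vector of channel labels.
#' @return a re-referenced [epoch_array()].
#' @export
rereference <- function(epochs, scheme = "average") {
  d <- dim(epochs$data)
  if (identical(scheme, "average")) {
    j <- seq_len(d[2])
  } else {
    missing <- setdiff(scheme, epochs$channel_labels)
    if (length(missing))
      stop("unknown reference channel(s): ", paste(missing, collapse = ", "))
    j <- match(scheme, epochs$channel_labels)
  }
  out <- epochs$data
  for (tr in seq_len(d[1])) {
    ref <- colMeans(matrix(out[tr, j, ], nrow = length(j)))
    out[tr, , ] <- sweep(matrix(out[tr, , ], nrow = d[2]), 2, ref)
  }
  epoch_array(out, epochs$fs, epochs$window, epochs$channel_labels,
              epochs$condition_labels, epochs$participant_ids)
}
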