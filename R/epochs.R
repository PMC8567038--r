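#' Epoched multichannel EEG container
#'
#' An `epoch_array` holds a trials x channels x samples tensor of epoched EEG
#' (microvolts) together with its sampling rate, epoch window relative to
#' stimulus onset, channel labels and per-trial condition labels. All
#' preprocessing, ERP and network operations in this package consume and
#' return `epoch_array` objects.
#'
#' The ms-to-sample convention is half-open: a window `[a, b)` in ms maps to
#' sample indices `floor((t - window[1]) * fs / 1000)` (0-based), so an epoch
#' on `[-200, 800)` ms at 500 Hz holds exactly 500 samples.
#'
#' @param data numeric array, trials x channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param window length-2 numeric, epoch window in ms relative to onset,
#'   interpreted as the half-open interval `[window[1], window[2])`.
#' @param channel_labels character vector of unique channel names (10-20
#'   labels for real recordings).
#' @param condition_labels character or factor of length `n_trials`
#'   (e.g. `"LAI"` / `"HAI"`), or `NULL`.
#' @param participant_ids optional per-trial participant identifiers.
#'
#' @return An object of class `epoch_array`.
#' @export
epoch_array <- function(data, fs, window, channel_labels,
                        condition_labels = NULL, participant_ids = NULL) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-d array: trials x channels x samples")
  storage.mode(data) <- "double"
  n_trials   <- dim(data)[1L]
  n_channels <- dim(data)[2L]
  n_samples  <- dim(data)[3L]
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  if (length(window) != 2L || window[2] <= window[1])
    stop("`window` must be c(start_ms, end_ms) with end > start")
  expected <- round((window[2] - window[1]) * fs / 1000)
  if (n_samples != expected)
    stop(sprintf("sample count %d does not match window %g..%g ms at %g Hz (expected %d)",
                 n_samples, window[1], window[2], fs, expected))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != n_channels)
    stop("length(channel_labels) must equal dim(data)[2]")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  if (!is.null(condition_labels)) {
    condition_labels <- as.character(condition_labels)
    if (length(condition_labels) != n_trials)
      stop("condition label count must equal trial count")
  }
  if (!is.null(participant_ids)) {
    participant_ids <- as.character(participant_ids)
    if (length(participant_ids) != n_trials)
      stop("participant id count must equal trial count")
  }
  dimnames(data) <- list(NULL, channel_labels, NULL)
  structure(
    list(data = data, fs = fs, window = as.numeric(window),
         channel_labels = channel_labels,
         condition_labels = condition_labels,
         participant_ids = participant_ids),
    class = "epoch_array"
  )
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_array> %d trial(s), %d channel(s), %d sample(s) @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  window: [%g, %g) ms\n", x$window[1], x$window[2]))
  if (!is.null(x$condition_labels)) {
    tab <- table(x$condition_labels)
    cat("  conditions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.epoch_array <- function(x) dim(x$data)

#' Number of trials in an epoch_array
#' @param epochs an `epoch_array`.
#' @return integer trial count.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1L]

#' Epoch time axis
#'
#' Sample times in ms for each stored sample, under the half-open window
#' convention (first sample at `window[1]`, step `1000/fs`).
#'
#' @param epochs an `epoch_array`.
#' @return numeric vector of times in ms, length = samples.
#' @export
epoch_times <- function(epochs) {
  n <- dim(epochs$data)[3L]
  epochs$window[1] + (seq_len(n) - 1) * 1000 / epochs$fs
}

#' Map a ms interval to sample indices
#'
#' Half-open convention: `[a, b)` ms selects samples with
#' `floor((t - window_start) * fs / 1000)` in `[floor((a-w0)fs/1000),
#' floor((b-w0)fs/1000))`, returned 1-based.
#'
#' @param epochs an `epoch_array` (or anything with `fs` and `window`).
#' @param interval length-2 ms interval `[a, b)`.
#' @return integer vector of 1-based sample indices.
#' @export
ms_to_samples <- function(epochs, interval) {
  if (length(interval) != 2L || interval[2] <= interval[1])
    stop("`interval` must be c(a, b) ms with b > a")
  w0 <- epochs$window[1]; fs <- epochs$fs
  if (interval[1] < epochs$window[1] || interval[2] > epochs$window[2])
    stop(sprintf("interval [%g, %g) ms lies outside the epoch window [%g, %g)",
                 interval[1], interval[2], epochs$window[1], epochs$window[2]))
  from <- floor((interval[1] - w0) * fs / 1000)
  to   <- floor((interval[2] - w0) * fs / 1000)  # exclusive
  if (to <= from) stop("interval contains no samples at this sampling rate")
  seq.int(from + 1L, to)
}

#' Subset trials of an epoch_array
#' @param epochs an `epoch_array`.
#' @param idx integer or logical trial index.
#' @return an `epoch_array` with the selected trials.
#' @export
subset_trials <- function(epochs, idx) {
  epoch_array(epochs$data[idx, , , drop = FALSE], epochs$fs, epochs$window,
              epochs$channel_labels,
              if (!is.null(epochs$condition_labels)) epochs$condition_labels[idx],
              if (!is.null(epochs$participant_ids)) epochs$participant_ids[idx])
}

#' Select channels of an epoch_array
#' @param epochs an `epoch_array`.
#' @param channels character vector of channel labels to keep (order respected).
#' @return an `epoch_array` restricted to `channels`.
#' @export
select_channels <- function(epochs, channels) {
  missing <- setdiff(channels, epochs$channel_labels)
  if (length(missing))
    stop("unknown channel(s): ", paste(missing, collapse = ", "))
  j <- match(channels, epochs$channel_labels)
  epoch_array(epochs$data[, j, , drop = FALSE], epochs$fs, epochs$window,
              channels, epochs$condition_labels, epochs$participant_ids)
}

#' Standard 32-channel 10-20 montage
#'
#' Channel labels of a standard 32-electrode cap (10-20 extension), including
#' the mastoid pair TP9/TP10 used for linked-mastoid re-referencing.
#'
#' @return character vector of 32 labels.
#' @export
montage_32 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
    "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
    "O1", "Oz", "O2", "TP9", "TP10", "FT9", "FT10")
}

#' Default 20-electrode subset for network construction
#'
#' The canonical 10-20 electrodes used to build directed networks (volume
#' conduction is mitigated by restricting to a sparse whole-scalp subset).
#' The 20th electrode defaults to Oz and is configurable.
#'
#' @param extra the 20th label, `"Oz"` (default) or `"FCz"`.
#' @return character vector of 20 labels.
#' @export
network_montage_20 <- function(extra = c("Oz", "FCz")) {
  extra <- match.arg(extra)
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3", "Cz",
    "C4", "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "O2", extra)
}
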