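# shared fixture builders (all generated in code; no stored data)

white_epochs <- function(n_trials = 3, n_channels = 2, n_samples = 500,
                         fs = 500, seed = 1, sd = 1,
                         conditions = NULL) {
  set.seed(seed)
  window <- c(0, n_samples * 1000 / fs)
  epoch_array(array(rnorm(n_trials * n_channels * n_samples, sd = sd),
                    c(n_trials, n_channels, n_samples)),
              fs, window, paste0("ch", seq_len(n_channels)),
              condition_labels = conditions)
}

# fully crossed amplitude table with optional injected condition effect
amplitude_fixture <- function(n_sub = 4, n_elec = 3, effect = 0.5,
                              effect_electrodes = seq_len(n_elec),
                              noise = 1, seed = 1) {
  set.seed(seed)
  tab <- expand.grid(participant = sprintf("s%02d", seq_len(n_sub)),
                     condition = c("LAI", "HAI"),
                     electrode = paste0("e", seq_len(n_elec)),
                     stringsAsFactors = FALSE)
  subj_int <- rnorm(n_sub)  # participant random intercepts
  tab$amplitude <- subj_int[match(tab$participant, unique(tab$participant))] +
    rnorm(nrow(tab), sd = noise) +
    ifelse(tab$condition == "LAI" &
             tab$electrode %in% paste0("e", effect_electrodes), effect, 0)
  tab
}

# writes a minimal BrainVision triplet; returns the .vhdr path
write_brainvision_fixture <- function(dir, data, fs = 500,
                                      labels = rownames(data),
                                      markers = integer(),
                                      format = c("IEEE_FLOAT_32", "INT_16"),
                                      resolution = 0.1,
                                      marker_file = TRUE) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  eeg <- file.path(dir, "rec.eeg")
  if (format == "IEEE_FLOAT_32") {
    writeBin(as.numeric(as.vector(data)), eeg, size = 4, endian = "little")
    res_field <- ""
  } else {
    writeBin(as.integer(round(as.vector(data) / resolution)), eeg, size = 2,
             endian = "little")
    res_field <- as.character(resolution)
  }
  ch_lines <- sprintf("Ch%d=%s,,%s,µV", seq_len(nrow(data)), labels, res_field)
  writeLines(c("Brain Vision Data Exchange Header File Version 1.0",
               "[Common Infos]",
               "DataFile=rec.eeg",
               if (marker_file) "MarkerFile=rec.vmrk",
               "DataFormat=BINARY",
               "DataOrientation=MULTIPLEXED",
               sprintf("NumberOfChannels=%d", nrow(data)),
               sprintf("SamplingInterval=%d", as.integer(1e6 / fs)),
               "[Binary Infos]",
               sprintf("BinaryFormat=%s", format),
               "[Channel Infos]",
               ch_lines),
             file.path(dir, "rec.vhdr"))
  if (marker_file) {
    mk <- c("[Marker Infos]", "Mk1=New Segment,,1,1,0")
    if (length(markers))
      mk <- c(mk, sprintf("Mk%d=Stimulus,S  1,%d,1,0",
                          seq_along(markers) + 1L, markers))
    writeLines(mk, file.path(dir, "rec.vmrk"))
  }
  file.path(dir, "rec.vhdr")
}

# single-sinusoid epoch helper
sine_epoch <- function(freq, fs = 500, window = c(-200, 800), amp = 1) {
  n <- round((window[2] - window[1]) * fs / 1000)
  t <- (window[1] + (seq_len(n) - 1) * 1000 / fs) / 1000
  epoch_array(array(amp * sin(2 * pi * freq * t), c(1, 1, n)), fs, window, "Cz")
}
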