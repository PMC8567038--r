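#' Read a BrainVision recording
#'
#' Minimal reader for the BrainVision triplet: an INI-style text header
#' (`.vhdr`), a text marker file (`.vmrk`) and a binary data file (`.eeg`).
#' Supports multiplexed `IEEE_FLOAT_32` and `INT_16` data (the common export
#' formats); INT_16 values are scaled by the per-channel resolution. Output
#' units are microvolts.
#'
#' @param vhdr_path path to the `.vhdr` header.
#' @return `list(data = channels x samples matrix, fs, channel_labels,
#'   markers = data.frame(type, description, position))`.
#' @export
read_brainvision <- function(vhdr_path) {
  if (!file.exists(vhdr_path)) stop("header not found: ", vhdr_path)
  ini <- parse_ini(readLines(vhdr_path, warn = FALSE))
  ci <- ini[["Common Infos"]]
  for (field in c("DataFile", "NumberOfChannels", "SamplingInterval"))
    if (is.null(ci[[field]]))
      stop("malformed BrainVision header: missing field ", field)
  if (!is.null(ci$DataFormat) && toupper(ci$DataFormat) != "BINARY")
    stop("malformed BrainVision header: unsupported DataFormat ", ci$DataFormat)
  if (!is.null(ci$DataOrientation) && toupper(ci$DataOrientation) != "MULTIPLEXED")
    stop("malformed BrainVision header: unsupported DataOrientation ",
         ci$DataOrientation)
  n_ch <- as.integer(ci$NumberOfChannels)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)  # SamplingInterval is in us
  chinfo <- ini[["Channel Infos"]]
  labels <- character(n_ch); resolution <- rep(1, n_ch)
  for (k in seq_len(n_ch)) {
    entry <- chinfo[[paste0("Ch", k)]]
    if (is.null(entry)) stop("malformed BrainVision header: missing Ch", k)
    parts <- strsplit(entry, ",", fixed = TRUE)[[1L]]
    labels[k] <- parts[1L]
    if (length(parts) >= 3L && nzchar(parts[3L]))
      resolution[k] <- as.numeric(parts[3L])
  }
  fmt <- toupper(ini[["Binary Infos"]]$BinaryFormat %||% "IEEE_FLOAT_32")
  data_path <- file.path(dirname(vhdr_path), ci$DataFile)
  if (!file.exists(data_path)) stop("data file not found: ", data_path)
  sz <- file.info(data_path)$size
  raw_vals <- switch(fmt,
    IEEE_FLOAT_32 = readBin(data_path, "double", n = sz / 4, size = 4,
                            endian = "little"),
    INT_16 = readBin(data_path, "integer", n = sz / 2, size = 2, signed = TRUE,
                     endian = "little"),
    stop("malformed BrainVision header: unsupported BinaryFormat ", fmt))
  n_samp <- length(raw_vals) %/% n_ch
  data <- matrix(raw_vals[seq_len(n_ch * n_samp)], nrow = n_ch)  # multiplexed
  if (fmt == "INT_16") data <- data * resolution
  rownames(data) <- labels
  markers <- data.frame(type = character(), description = character(),
                        position = integer(), stringsAsFactors = FALSE)
  if (!is.null(ci$MarkerFile)) {
    vmrk_path <- file.path(dirname(vhdr_path), ci$MarkerFile)
    if (!file.exists(vmrk_path)) stop("marker file not found: ", vmrk_path)
    mk <- parse_ini(readLines(vmrk_path, warn = FALSE))[["Marker Infos"]]
    if (length(mk)) {
      rows <- lapply(mk, function(v) {
        parts <- strsplit(v, ",", fixed = TRUE)[[1L]]
        data.frame(type = parts[1L], description = parts[2L],
                   position = as.integer(parts[3L]), stringsAsFactors = FALSE)
      })
      markers <- do.call(rbind, rows); rownames(markers) <- NULL
    }
  }
  list(data = data, fs = fs, channel_labels = labels, markers = markers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_ini <- function(lines) {
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list(); section <- "GLOBAL"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      key <- trimws(substr(ln, 1, eq - 1))
      val <- trimws(substr(ln, eq + 1, nchar(ln)))
      out[[section]][[key]] <- val
    }
  }
  out
}

#' Read EEG input in either supported dialect
#'
#' @param path a `.vhdr` header (`dialect = "brainvision"`) or a directory of
#'   per-trial delimited matrices with an `epochs.json` sidecar
#'   (`dialect = "matrix-dir"`, the [write_epochs()] dialect).
#' @param dialect input dialect.
#' @return an [epoch_array()] for `matrix-dir`; a continuous-record list
#'   (see [read_brainvision()]) for `brainvision`.
#' @export
read_eeg <- function(path, dialect = c("matrix-dir", "brainvision")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         "matrix-dir" = read_epochs(path),
         "brainvision" = read_brainvision(path))
}

#' Default demonstration pipeline configuration
#'
#' A fully synthetic, self-contained configuration: ERP-like 32-channel
#' epochs on [-200, 800) ms at 500 Hz feed the ERP branch; a 3-node
#' switching-source time-varying MVAR fixture (driver switching from the
#' first to the second node mid-epoch) feeds the network branch at the 25 Hz
#' network rate; a paired log-normal response-time table feeds the
#' behavioural tests.
#'
#' @param seed integer seed driving every stochastic stage.
#' @param out_dir directory for result files.
#' @param work_dir directory where synthetic inputs are written.
#' @param n_erp_trials trials per condition for the ERP branch, default 60.
#' @param n_network_trials trials per condition for the network branch,
#'   default 20.
#' @param n_behavior_trials trials per condition for the behavioural table,
#'   default 200.
#' @return a nested config list (YAML-serialisable).
#' @export
default_demo_config <- function(seed = 1L, out_dir = "results",
                                work_dir = tempfile("adtfnet_demo_"),
                                n_erp_trials = 60L, n_network_trials = 20L,
                                n_behavior_trials = 200L) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    input = list(
      type = "synthetic",
      dialect = "matrix-dir",
      epochs_dir = file.path(work_dir, "erp_epochs"),
      network_epochs_dir = file.path(work_dir, "network_epochs"),
      behavior_path = file.path(work_dir, "behavior.tsv")
    ),
    simulate = list(
      n_erp_trials = as.integer(n_erp_trials),
      n_network_trials = as.integer(n_network_trials),
      n_behavior_trials = as.integer(n_behavior_trials),
      n_participants = 10L,
      erp_noise_sd = 10
    ),
    montage = montage_32(),
    filter = list(low = 0.1, high = 30),
    epoch_window = c(-200, 800),
    baseline = c(-200, 0),
    reject_threshold = 75,
    reference = "average",
    components = list(
      P2  = list(window = c(140, 200),
                 electrodes = c("F3", "F4", "FC1", "FC2", "Fz", "C3", "C4", "Cz")),
      P3  = list(window = c(300, 400),
                 electrodes = c("C3", "C4", "CP1", "CP2", "Cz", "P3", "P4", "Pz")),
      LPC = list(window = c(500, 700),
                 electrodes = c("F3", "F4", "FC1", "FC2", "Fz", "C3", "C4", "Cz"))
    ),
    network = list(
      target_fs = 25,
      p = 1,
      p_range = c(1, 3),
      update_constant = 0.02,
      freqs = 1:10,
      band = c(1, 10),
      window = c(0, 4000),
      switch_ms = 2000,
      substages = list(stage_A = c(1000, 2000), stage_B = c(3000, 4000)),
      top_k = 10
    )
  )
}

#' Ground-truth schedule of the switching-source network fixture
#'
#' Three channels; in the first segment node 1 drives nodes 2 and 3
#' (off-diagonal coefficients 0.5, diagonals 0.5), in the second segment node
#' 2 drives nodes 1 and 3. Both segments are stable (companion spectral
#' radius < 1) and innovations are unit white noise.
#'
#' @param window ms interval the segments tile, default `c(0, 4000)`.
#' @param switch_ms boundary between the segments, default 2000.
#' @param coupling driver-to-target coefficient, default 0.5.
#' @param diag_coef self-coefficient, default 0.5.
#' @return a [coefficient_schedule()].
#' @export
switching_source_schedule <- function(window = c(0, 4000), switch_ms = 2000,
                                      coupling = 0.5, diag_coef = 0.5) {
  A1 <- diag(diag_coef, 3); A1[2, 1] <- coupling; A1[3, 1] <- coupling
  A2 <- diag(diag_coef, 3); A2[1, 2] <- coupling; A2[3, 2] <- coupling
  coefficient_schedule(
    order = 1L,
    segments = list(
      list(interval = c(window[1], switch_ms), A = list(A1)),
      list(interval = c(switch_ms, window[2]), A = list(A2))
    ),
    noise_covariance = diag(3))
}

#' Generate the synthetic inputs a demo config points at
#'
#' Writes ERP epochs, switching-source network epochs (both conditions share
#' the ground truth, emulating two task recordings) and the behavioural table
#' to the paths named in `config$input`.
#'
#' @param config a [default_demo_config()]-shaped config with
#'   `input$type == "synthetic"`.
#' @return invisibly, the config.
#' @export
simulate_inputs <- function(config) {
  stopifnot(identical(config$input$type, "synthetic"))
  seed <- config$seed
  templates <- erp_template_set(channel_labels = config$montage,
                                fs = 500, window = config$epoch_window,
                                noise_sd = config$simulate$erp_noise_sd)
  erp <- make_erp_epochs(templates, config$simulate$n_erp_trials, seed,
                         n_participants = config$simulate$n_participants)
  write_epochs(erp, config$input$epochs_dir)

  sched <- switching_source_schedule(window = config$network$window,
                                     switch_ms = config$network$switch_ms)
  nets <- lapply(c("LAI", "HAI"), function(cond) {
    simulate_tvmvar(sched, config$simulate$n_network_trials, 3,
                    fs = config$network$target_fs,
                    window = config$network$window,
                    seed = seed + if (cond == "LAI") 0L else 17L,
                    condition = cond)
  })
  combined <- epoch_array(
    abind3(nets[[1]]$data, nets[[2]]$data),
    config$network$target_fs, config$network$window,
    nets[[1]]$channel_labels,
    condition_labels = c(nets[[1]]$condition_labels, nets[[2]]$condition_labels))
  attr(combined, "schedule") <- sched
  write_epochs(combined, config$input$network_epochs_dir)

  behavior <- simulate_behavior(config$simulate$n_behavior_trials, seed = seed)
  write_behavior(behavior, config$input$behavior_path)
  invisible(config)
}

# bind two trials x channels x samples arrays along trials
abind3 <- function(a, b) {
  out <- array(0, dim = c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

#' Validate a pipeline configuration
#'
#' Checks internal consistency before any computation: baseline inside the
#' epoch window, component windows inside the epoch window, filter band below
#' Nyquist, ADTF band below the network-rate Nyquist, known reference
#' channels, positive rejection threshold.
#'
#' @param config a config list.
#' @param fs acquisition sampling rate the ERP branch runs at, default 500.
#' @return invisibly `TRUE`; stops with a named message on the first violation.
#' @export
validate_config <- function(config, fs = 500) {
  w <- config$epoch_window
  if (is.null(w) || length(w) != 2L || w[2] <= w[1])
    stop("config: epoch_window must be c(start_ms, end_ms)")
  b <- config$baseline
  if (b[1] < w[1] || b[2] > w[2] || b[2] <= b[1])
    stop("config: baseline must be a nonempty interval inside the epoch window")
  if (!is.null(config$filter)) {
    if (!(config$filter$low > 0 && config$filter$low < config$filter$high &&
          config$filter$high < fs / 2))
      stop("config: filter band must satisfy 0 < low < high < fs/2")
  }
  if (!is.null(config$reject_threshold) && config$reject_threshold <= 0)
    stop("config: reject_threshold must be positive")
  for (nm in names(config$components)) {
    cw <- config$components[[nm]]
    if (cw$window[1] < w[1] || cw$window[2] > w[2])
      stop("config: component window ", nm, " lies outside the epoch window")
    unknown <- setdiff(cw$electrodes, config$montage)
    if (length(unknown))
      stop("config: component ", nm, " references unknown electrode(s): ",
           paste(unknown, collapse = ", "))
  }
  if (!identical(config$reference, "average")) {
    unknown <- setdiff(config$reference, config$montage)
    if (length(unknown))
      stop("config: unknown reference channel(s): ",
           paste(unknown, collapse = ", "))
  }
  nw <- config$network
  if (!is.null(nw)) {
    if (max(nw$band) >= nw$target_fs / 2)
      stop("config: ADTF band must lie below the network-rate Nyquist")
    if (any(nw$freqs >= nw$target_fs / 2))
      stop("config: frequency grid must lie below the network-rate Nyquist")
    if (nw$update_constant <= 0 || nw$update_constant >= 1)
      stop("config: update_constant must lie in (0, 1)")
  }
  invisible(TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the three branches of the analysis on the inputs a config names:
#' preprocessing + ERP statistics (band-pass filter, baseline correction,
#' artifact rejection, re-referencing; grand averages, per-component mean
#' amplitudes, 2 x K repeated-measures ANOVA with Greenhouse-Geisser
#' correction, per-electrode post-hoc contrasts), behavioural summary with
#' Wilcoxon signed-rank test, and the time-varying network branch (Kalman
#' tv-MVAAR, ADTF, band integration, per-condition averaging, substage
#' source-node summaries). Deterministic given config + seed.
#'
#' @param config a config list (see [default_demo_config()]); synthetic
#'   inputs are generated first when `input$type == "synthetic"`.
#' @return a result bundle list: `grand_averages`, `amplitudes`, `anova`,
#'   `posthoc`, `peak_latency`, `behavior`, `networks`, `summaries`,
#'   `rejection`, `manifest`.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  if (identical(config$input$type, "synthetic")) simulate_inputs(config)

  log_msg <- function(...) message(sprintf(...))
  bundle <- list()

  # --- ERP branch -----------------------------------------------------------
  epochs <- tryCatch(read_eeg(config$input$epochs_dir, config$input$dialect),
                     error = function(e) stop("stage read_eeg: ", conditionMessage(e)))
  log_msg("erp: %d trials in", n_trials(epochs))
  erp <- tryCatch({
    x <- bandpass_filter(epochs, config$filter$low, config$filter$high)
    x <- baseline_correct(x, config$baseline)
    rej <- reject_artifacts(x, config$reject_threshold)
    x <- rereference(rej$epochs, config$reference)
    list(epochs = x, report = rej$report)
  }, error = function(e) stop("stage preprocessing: ", conditionMessage(e)))
  log_msg("erp: %d trials kept after +/-%g uV rejection",
          n_trials(erp$epochs), config$reject_threshold)
  bundle$rejection <- erp$report

  bundle$grand_averages <- grand_average(erp$epochs)
  windows <- lapply(names(config$components), function(nm) {
    cw <- config$components[[nm]]
    component_window(nm, cw$window, cw$electrodes)
  })
  names(windows) <- names(config$components)
  bundle$amplitudes <- lapply(windows, function(w) mean_amplitude(erp$epochs, w))
  if (!is.null(erp$epochs$participant_ids)) {
    # paired design only exists when participants saw both conditions
    bundle$anova <- tryCatch(lapply(bundle$amplitudes, rm_anova_2xK),
                             error = function(e) stop("stage erp_stats: ", conditionMessage(e)))
    bundle$posthoc <- lapply(bundle$amplitudes, posthoc_by_electrode)
  } else {
    log_msg("erp: no participant ids; skipping within-subject ANOVA / post-hoc")
  }
  if ("P3" %in% names(windows) && "Cz" %in% epochs$channel_labels) {
    ga <- bundle$grand_averages
    bundle$peak_latency <- lapply(ga, function(w)
      peak_latency(w, "Cz", windows$P3$window, fs = attr(ga, "fs"),
                   epoch_window = attr(ga, "window")))
  }

  # --- behavioural branch ---------------------------------------------------
  if (!is.null(config$input$behavior_path)) {
    behavior <- read_behavior(config$input$behavior_path)
    bundle$behavior <- behavior_stats(behavior)
    log_msg("behavior: Z = %.2f, p = %.3g",
            bundle$behavior$test$Z, bundle$behavior$test$p)
  }

  # --- network branch -------------------------------------------------------
  if (!is.null(config$input$network_epochs_dir)) {
    nepochs <- tryCatch(read_eeg(config$input$network_epochs_dir, config$input$dialect),
                        error = function(e) stop("stage read_eeg(network): ",
                                                 conditionMessage(e)))
    if (nepochs$fs > config$network$target_fs)
      nepochs <- downsample(nepochs, config$network$target_fs)
    log_msg("network: %d trials at %g Hz", n_trials(nepochs), nepochs$fs)
    tn <- tryCatch(
      trial_networks(nepochs, p = config$network$p,
                     p_range = config$network$p_range,
                     update_constant = config$network$update_constant,
                     freqs = config$network$freqs, band = config$network$band),
      error = function(e) stop("stage tv_network: ", conditionMessage(e)))
    nets <- tn$networks
    if (inherits(nets, "integrated_network")) nets <- list(pooled = nets)
    bundle$networks <- nets
    bundle$summaries <- lapply(nets, function(nw)
      summarize_substages(nw, stages = config$network$substages,
                          channel_labels = nepochs$channel_labels,
                          epoch_window = nepochs$window,
                          top_k = config$network$top_k))
    bundle$model_order <- tn$p
  }

  bundle$manifest <- build_manifest(config)
  bundle
}

build_manifest <- function(config) {
  inputs <- unlist(config$input[c("epochs_dir", "network_epochs_dir", "behavior_path")])
  digests <- list()
  for (p in inputs) {
    if (is.null(p)) next
    files <- if (dir.exists(p)) list.files(p, full.names = TRUE) else p
    files <- files[file.exists(files)]
    if (length(files)) digests[[p]] <- unname(tools::md5sum(files))
  }
  list(config = config, seed = config$seed,
       package_version = as.character(utils::packageVersion("adtfnet")),
       r_version = as.character(getRversion()),
       input_digests = digests)
}

#' Write a result bundle to disk
#'
#' Serialises every artifact of [run_pipeline()]: per-condition grand-average
#' waveforms and integrated-network edge lists as tab-separated text,
#' amplitude/ANOVA/post-hoc tables as TSV, behavioural and substage summaries
#' plus the provenance manifest as JSON.
#'
#' @param bundle a [run_pipeline()] result.
#' @param outdir output directory.
#' @param overwrite allow writing into a non-empty directory, default FALSE.
#' @return invisibly, the paths written.
#' @export
write_results <- function(bundle, outdir, overwrite = FALSE) {
  if (dir.exists(outdir) && length(list.files(outdir)) && !overwrite)
    stop("output directory ", outdir, " is not empty (use overwrite = TRUE)")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wtsv <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  wjson <- function(x, name) {
    p <- file.path(outdir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    paths <<- c(paths, p)
  }
  if (!is.null(bundle$grand_averages)) {
    for (cond in names(bundle$grand_averages)) {
      m <- bundle$grand_averages[[cond]]
      df <- data.frame(channel = rownames(m), m, check.names = FALSE)
      wtsv(df, sprintf("grand_average_%s.tsv", cond))
    }
  }
  for (nm in names(bundle$amplitudes))
    wtsv(bundle$amplitudes[[nm]], sprintf("amplitude_%s.tsv", nm))
  for (nm in names(bundle$anova)) {
    a <- bundle$anova[[nm]]; class(a) <- "data.frame"
    wtsv(a, sprintf("anova_%s.tsv", nm))
  }
  for (nm in names(bundle$posthoc))
    wtsv(bundle$posthoc[[nm]], sprintf("posthoc_%s.tsv", nm))
  if (!is.null(bundle$behavior)) {
    wtsv(bundle$behavior$summary, "behavior_summary.tsv")
    wjson(bundle$behavior$test, "behavior_test.json")
  }
  if (!is.null(bundle$networks)) {
    for (cond in names(bundle$networks))
      wtsv(network_edge_list(bundle$networks[[cond]]),
           sprintf("network_%s.tsv", cond))
  }
  if (!is.null(bundle$summaries)) {
    summ <- lapply(bundle$summaries, function(s)
      lapply(unclass(s), function(st) {
        st$outflow <- as.list(st$outflow); st
      }))
    wjson(summ, "network_summaries.json")
  }
  if (!is.null(bundle$rejection)) wjson(unclass(bundle$rejection), "rejection.json")
  wjson(bundle$manifest, "manifest.json")
  invisible(paths)
}

#' Long-format edge list of an integrated network
#'
#' One row per (time point, source, target) triple, including self-edges, so
#' the row count is targets x sources x time points.
#'
#' @param network an `integrated_network`.
#' @param epoch_window epoch window ms for the time axis, default `c(-200, 800)`
#'   unless the network's own grid is passed through.
#' @return data.frame with columns `time_ms`, `source`, `target`, `theta2`.
#' @export
network_edge_list <- function(network, epoch_window = NULL) {
  d <- dim(network$theta2)
  labels <- dimnames(network$theta2)[[1]] %||% paste0("ch", seq_len(d[1]))
  t_ms <- network$time_points  # sample indices on the network-rate grid
  if (!is.null(epoch_window))
    t_ms <- epoch_window[1] + (network$time_points - 1) * 1000 / network$fs
  grid <- expand.grid(target = labels, source = labels, ti = seq_len(d[3]),
                      stringsAsFactors = FALSE)
  data.frame(time_ms = t_ms[grid$ti], source = grid$source,
             target = grid$target,
             theta2 = network$theta2[cbind(match(grid$target, labels),
                                           match(grid$source, labels), grid$ti)],
             stringsAsFactors = FALSE)
}

#' Read / write a pipeline config as YAML
#'
#' @param path YAML file path.
#' @param config config list.
#' @return `read_config` returns the config list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
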