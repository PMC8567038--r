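#!/usr/bin/env Rscript
# Network branch: per-trial Kalman tv-MVAAR fits, ADTF, 1-10 Hz band
# integration, per-condition averaging, and substage source-node summaries on
# the switching-source epochs. Run 01_simulate.R first.

suppressMessages(library(adtfnet))

cfg <- read_config("results/pipeline_config.yaml")
epochs <- read_epochs(cfg$input$network_epochs_dir)
if (epochs$fs > cfg$network$target_fs)
  epochs <- downsample(epochs, cfg$network$target_fs)

tn <- trial_networks(epochs, p = cfg$network$p,
                     p_range = cfg$network$p_range,
                     update_constant = cfg$network$update_constant,
                     freqs = cfg$network$freqs, band = cfg$network$band)
nets <- tn$networks
if (inherits(nets, "integrated_network")) nets <- list(pooled = nets)

for (cond in names(nets)) {
  write.table(network_edge_list(nets[[cond]], epoch_window = epochs$window),
              sprintf("results/network_%s.tsv", cond), sep = "\t",
              row.names = FALSE, quote = FALSE)
  s <- summarize_substages(nets[[cond]], stages = cfg$network$substages,
                           channel_labels = epochs$channel_labels,
                           epoch_window = epochs$window,
                           top_k = cfg$network$top_k)
  for (st in s)
    message(sprintf("%s / %s [%g, %g) ms: source node %s (outflow %.2f)",
                    cond, st$stage, st$interval_ms[1], st$interval_ms[2],
                    st$source, max(st$outflow)))
  jsonlite::write_json(
    lapply(unclass(s), function(st) { st$outflow <- as.list(st$outflow); st }),
    sprintf("results/network_summary_%s.json", cond),
    auto_unbox = TRUE, digits = NA, force = TRUE)
}
message(sprintf("model order p = %d, band [%g, %g] Hz, %d trials per condition",
                tn$p, cfg$network$band[1], cfg$network$band[2],
                n_trials(epochs) / length(nets)))
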