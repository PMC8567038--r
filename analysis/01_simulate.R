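#!/usr/bin/env Rscript
# Generates the synthetic study inputs: ERP-like 32-channel epochs for the two
# information-load conditions, the 3-node switching-source MVAR epochs for the
# network branch, and the paired log-normal response-time table. All later
# drivers read these files, so the whole analysis is reproducible offline.

suppressMessages(library(adtfnet))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

cfg <- default_demo_config(seed = seed, out_dir = "results",
                           work_dir = "results/inputs")
dir.create("results", showWarnings = FALSE)
validate_config(cfg)
simulate_inputs(cfg)
write_config(cfg, "results/pipeline_config.yaml")

erp <- read_epochs(cfg$input$epochs_dir)
net <- read_epochs(cfg$input$network_epochs_dir)
beh <- read_behavior(cfg$input$behavior_path)
message(sprintf(
  "simulated %d ERP trials (%d channels), %d network trials (%d channels), %d RT rows; config at results/pipeline_config.yaml",
  n_trials(erp), length(erp$channel_labels),
  n_trials(net), length(net$channel_labels), nrow(beh)))
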