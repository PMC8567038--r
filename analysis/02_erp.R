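#!/usr/bin/env Rscript
# ERP branch: preprocesses the simulated epochs (0.1-30 Hz zero-phase
# band-pass, [-200, 0) ms baseline, +/-75 uV artifact rejection, average
# re-reference), then quantifies P2 / P3 / LPC window amplitudes and runs the
# 2 x 8 within-subject ANOVA with Greenhouse-Geisser correction plus
# per-electrode post-hoc contrasts. Run 01_simulate.R first.

suppressMessages(library(adtfnet))

cfg <- read_config("results/pipeline_config.yaml")
epochs <- read_epochs(cfg$input$epochs_dir)

x <- bandpass_filter(epochs, cfg$filter$low, cfg$filter$high)
x <- baseline_correct(x, cfg$baseline)
rej <- reject_artifacts(x, cfg$reject_threshold)
x <- rereference(rej$epochs, cfg$reference)
message(sprintf("kept %d / %d trials after +/-%g uV rejection",
                n_trials(x), n_trials(epochs), cfg$reject_threshold))

ga <- grand_average(x)
for (cond in names(ga))
  write.table(data.frame(channel = rownames(ga[[cond]]), ga[[cond]],
                         check.names = FALSE),
              sprintf("results/grand_average_%s.tsv", cond),
              sep = "\t", row.names = FALSE, quote = FALSE)

for (nm in names(cfg$components)) {
  cw <- component_window(nm, cfg$components[[nm]]$window,
                         cfg$components[[nm]]$electrodes)
  tab <- mean_amplitude(x, cw)
  write.table(tab, sprintf("results/amplitude_%s.tsv", nm), sep = "\t",
              row.names = FALSE, quote = FALSE)
  a <- rm_anova_2xK(tab)
  write.table(as.data.frame(a), sprintf("results/anova_%s.tsv", nm),
              sep = "\t", row.names = FALSE, quote = FALSE)
  ph <- posthoc_by_electrode(tab)
  write.table(ph, sprintf("results/posthoc_%s.tsv", nm), sep = "\t",
              row.names = FALSE, quote = FALSE)
  i <- which(a$effect == "condition")
  lai <- mean(tab$amplitude[tab$condition == "LAI"])
  hai <- mean(tab$amplitude[tab$condition == "HAI"])
  message(sprintf(
    "%s: LAI %.2f uV vs HAI %.2f uV; condition F(%d, %d) = %.2f, GG p = %.4f, pes = %.3f",
    nm, lai, hai, a$df1[i], a$df2[i], a$F[i], a$p_gg[i], a$pes[i]))
}

pk <- peak_latency(ga[["LAI"]], "Cz", cfg$components$P3$window,
                   fs = attr(ga, "fs"), epoch_window = attr(ga, "window"))
message(sprintf("LAI P3 peak at Cz: %.0f ms (%.2f uV)", pk$latency_ms, pk$amplitude))
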