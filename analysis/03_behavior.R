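#!/usr/bin/env Rscript
# Behavioural branch: per-condition response-time summaries and the paired
# Wilcoxon signed-rank test on trial-matched RTs. Run 01_simulate.R first.

suppressMessages(library(adtfnet))

cfg <- read_config("results/pipeline_config.yaml")
beh <- read_behavior(cfg$input$behavior_path)
st <- behavior_stats(beh)

write.table(st$summary, "results/behavior_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
jsonlite::write_json(st$test, "results/behavior_test.json", auto_unbox = TRUE,
                     digits = NA)

s <- st$summary
message(sprintf(
  "RT: HAI mean %.0f ms (median %.0f) vs LAI mean %.0f ms (median %.0f); Wilcoxon Z = %.2f, p = %.3g (%d pairs)",
  s$mean_rt[s$condition == "HAI"], s$median_rt[s$condition == "HAI"],
  s$mean_rt[s$condition == "LAI"], s$median_rt[s$condition == "LAI"],
  st$test$Z, st$test$p, st$test$n))
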