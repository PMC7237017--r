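#!/usr/bin/env Rscript
# Stage 2 — predictor screening.
#
# Pearson-correlation clustering of the candidate variables (single
# linkage on 1 - |r|, cut at 0.3) plus a jackknife contribution test:
# each variable is fit alone and left out in turn, scored by training
# AUC. One representative per correlation group is kept, and the
# dry-season precipitation variable is always retained.

source("analysis/00_config.R")

selected <- run_stage(cfg, "select-vars", run_dir)
jack <- read.csv(file.path(run_dir, "jackknife.csv"))

message("jackknife contribution (training AUC):")
for (i in seq_len(nrow(jack))) {
  message(sprintf("  %-6s alone %.3f  without %.3f", jack$variable[i],
                  jack$alone_score[i], jack$without_score[i]))
}
message("selected variables: ", paste(selected, collapse = ", "))
publish("correlation_matrix.csv", "dendrogram_merges.csv",
        "jackknife.csv", "selected_variables.txt")
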