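#!/usr/bin/env Rscript
# Stage 3 — ensemble model fitting.
#
# For each taxon: presence records thinned to one per cell, uniform
# background sample (10 per presence, floor 1000), then 30 bootstrap
# replicates of each of the four algorithm families (GLM, RF,
# MARS-style hinge regression, regularized maxent surrogate), each
# scored out-of-bag with AUC and TSS. Replicates are weighted by TSS in
# all later ensemble averaging.

source("analysis/00_config.R")

evaluation <- run_stage(cfg, "fit", run_dir)

message("mean out-of-bag skill by taxon and algorithm:")
for (i in seq_len(nrow(evaluation))) {
  message(sprintf("  %-12s %-7s AUC %.3f  TSS %.3f", evaluation$taxon[i],
                  evaluation$algorithm[i], evaluation$auc[i],
                  evaluation$tss[i]))
}
publish("evaluation.csv")
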