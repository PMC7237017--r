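#!/usr/bin/env Rscript
# Stage 1 — synthetic landscape.
#
# Generates the study system: four bioclim-style predictor surfaces for
# the current climate and for two past periods (Mid-Holocene, LGM) under
# three pseudo-GCMs; a patchy gypsum-soil mask; and 500 presence records
# for each of the three virtual taxa (two parents with overlapping
# niche margins, one intermediate hybrid), sampled from their known
# Gaussian response surfaces.

source("analysis/00_config.R")

stacks <- run_stage(cfg, "simulate", run_dir)
soil <- read_raster(file.path(run_dir, "soil.asc"))

message(sprintf("simulated %d predictor stacks on a %d x %d grid",
                length(stacks), cfg$scenario$grid$n_rows,
                cfg$scenario$grid$n_cols))
message(sprintf("soil mask covers %.1f%% of the landscape",
                100 * mean(soil$values)))
for (tx in names(cfg$taxa)) {
  occ <- read_occurrences(file.path(run_dir, "occurrences",
                                    paste0(tx, ".csv")))
  message(sprintf("  %s: %d presence records", tx, n_occurrences(occ)))
}
publish("scenario_metadata.json")
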