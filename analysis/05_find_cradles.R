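#!/usr/bin/env Rscript
# Stage 5 — locating the potential cradles.
#
# The low-suitability band comes from the parents' current-conditions
# suitability at their current occurrences: from the higher of the two
# minima to the higher of the two first quartiles (the combined rule).
# Cells of both parents' past-period consensus maps falling inside the
# band are each parent's low-suitability area (LSA); cradles are the
# gypsum-soil cells where the two LSAs overlap, located separately for
# the LGM and the Mid-Holocene.

source("analysis/00_config.R")

interval <- run_stage(cfg, "cradles", run_dir)

message(sprintf("low-suitability band (%s rule): [%.5f, %.5f]",
                interval$rule, interval$lower, interval$upper))
for (p in c("lgm", "mid_holocene")) {
  cells <- read.csv(file.path(run_dir, paste0("cradles_", p, ".csv")))
  message(sprintf("  %-12s %d potential cradle cell(s)", p, nrow(cells)))
}
publish("interval_report.csv", "cradles_lgm.csv", "cradles_mid_holocene.csv")
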