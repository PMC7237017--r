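#!/usr/bin/env Rscript
# Stage 6 — survival filter and expected current distribution.
#
# The survival threshold is the minimum of the hybrid's current-model
# suitability at its current occurrences (the weakest climate it
# demonstrably endures). Each cradle's hybrid suitability is tracked
# through the periods after its origin; survival is sequential, so a
# cradle extinguished at the Mid-Holocene stays extinguished. The
# survivors at the current period form the expected present-day
# distribution under the no-dispersal assumption, compared against the
# hybrid's occurrence cells.

source("analysis/00_config.R")

run_stage(cfg, "survive", run_dir)
report <- run_stage(cfg, "report", run_dir)

message(sprintf("survival threshold (%s): %.5f",
                report$coverage$threshold_mode,
                report$coverage$threshold_value))
for (p in c("lgm", "mid_holocene")) {
  message(sprintf("  %-12s %d cradle(s), %d survive to the present", p,
                  report$cradle_counts[[p]]$cradles,
                  report$cradle_counts[[p]]$surviving_to_current))
}
message(sprintf("expected distribution covers %.1f%% of occupied cells (radius %d)",
                100 * report$coverage$fraction_covered,
                report$coverage$radius_cells))
publish("trajectory_lgm.csv", "trajectory_mid_holocene.csv",
        "coverage.json", "report.json", "report.txt")
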