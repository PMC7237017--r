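#!/usr/bin/env Rscript
# Stage 4 — projection and GCM consensus.
#
# Each taxon's weighted ensemble predicts suitability on the current
# stack and on every past-period pseudo-GCM stack; per period the three
# GCM-specific maps are averaged into an unweighted consensus, with the
# cellwise standard deviation across GCMs kept as the uncertainty layer.

source("analysis/00_config.R")

run_stage(cfg, "project", run_dir)

for (tx in c(cfg$parents, cfg$hybrid)) {
  for (p in c("current", "mid_holocene", "lgm")) {
    m <- read_raster(file.path(run_dir, "suitability", tx,
                               paste0(p, "_mean.asc")))
    message(sprintf("  %-12s %-12s suitability mean %.3f max %.3f", tx, p,
                    mean(m$values, na.rm = TRUE),
                    max(m$values, na.rm = TRUE)))
  }
}
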