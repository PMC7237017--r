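# Shared configuration for the analysis scripts. The pipeline writes
# its working artifacts (including fitted-model bundles) under
# scratch/pipeline; the scripts copy the text tables a reader needs
# into results/.

library(cradlefinder)

cfg <- run_config(seed = 20200519)
run_dir <- "scratch/pipeline"
results_dir <- "results"
dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)

publish <- function(...) {
  for (f in c(...)) {
    file.copy(file.path(run_dir, f), file.path(results_dir, f),
              overwrite = TRUE)
  }
}
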