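#' Build a run configuration
#'
#' One object holding everything a full run needs: the synthetic
#' scenario (or paths to user data), the taxa, and every tunable knob
#' with its seed. The resolved configuration is echoed into each stage's
#' manifest so a run is reproducible from its run directory alone.
#'
#' @param seed base seed; all stage seeds derive from it.
#' @param scenario a `scenario_config` (default [default_scenario()]
#'   built from `seed`).
#' @param taxa named list of `virtual_taxon` objects (default
#'   [default_taxa()]).
#' @param parents names of the two parental taxa within `taxa`.
#' @param hybrid name of the hybrid taxon within `taxa`.
#' @param n_presences presence records sampled per taxon (default 500).
#' @param algorithms algorithm families (default all four).
#' @param n_replicates bootstrap replicates per algorithm (default 30).
#' @param background_multiplier,background_min background points =
#'   `max(multiplier * n_presences, background_min)`.
#' @param interval_rule `"combined"` (default) or `"union"`.
#' @param threshold_mode survival threshold mode: `"min"` (default),
#'   `"q1"` or `"mid"`.
#' @param forced_variables variables always kept by variable selection
#'   (default `"pdry"`, the dry-season precipitation slot).
#' @param select_variables whether the fit uses the selected subset
#'   (default TRUE).
#' @param weight_metric ensemble weighting statistic, `"tss"` or
#'   `"auc"`.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 20200519,
                       scenario = default_scenario(seed),
                       taxa = default_taxa(),
                       parents = c("parent_west", "parent_east"),
                       hybrid = "hybrid",
                       n_presences = 500,
                       algorithms = sdm_algorithms(),
                       n_replicates = 30,
                       background_multiplier = 10,
                       background_min = 1000,
                       interval_rule = c("combined", "union"),
                       threshold_mode = c("min", "q1", "mid"),
                       forced_variables = "pdry",
                       select_variables = TRUE,
                       weight_metric = c("tss", "auc")) {
  stopifnot(all(parents %in% names(taxa)), hybrid %in% names(taxa),
            length(parents) == 2)
  structure(list(
    seed = seed, scenario = scenario, taxa = taxa, parents = parents,
    hybrid = hybrid, n_presences = n_presences, algorithms = algorithms,
    n_replicates = n_replicates,
    background_multiplier = background_multiplier,
    background_min = background_min,
    interval_rule = match.arg(interval_rule),
    threshold_mode = match.arg(threshold_mode),
    forced_variables = forced_variables,
    select_variables = select_variables,
    weight_metric = match.arg(weight_metric)), class = "run_config")
}

#' Write the scalar settings of a run configuration to YAML
#'
#' The scenario and taxa are reconstructed from the seed on read, so the
#' YAML file plus the package version fully determine a run.
#'
#' @param config a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  scal <- config[setdiff(names(config), c("scenario", "taxa"))]
  yaml::write_yaml(scal, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file written by [write_run_config()] (keys may be a
#'   subset; missing keys take defaults).
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  scal <- yaml::read_yaml(path)
  do.call(run_config, scal)
}

.pipeline_stages <- c("simulate", "select-vars", "fit", "project",
                      "cradles", "survive", "report")

.stage_dir <- function(run_dir, ...) {
  d <- file.path(run_dir, ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

.stack_dir_write <- function(stack, dir) {
  for (v in names(stack$layers)) {
    write_raster(stack$layers[[v]], file.path(dir, paste0(v, ".asc")))
  }
}

.stack_dir_read <- function(dir, period, gcm) {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  layers <- lapply(files, read_raster)
  names(layers) <- sub("\\.asc$", "", basename(files))
  predictor_stack(layers, period = period, gcm = gcm)
}

# write the stage manifest: config echo, seeds, and md5 of every
# text output the stage produced
.write_manifest <- function(run_dir, stage, outputs, extra = list()) {
  outputs <- outputs[file.exists(outputs)]
  hashes <- tools::md5sum(outputs)
  manifest <- c(list(stage = stage,
                     outputs = as.list(stats::setNames(unname(hashes),
                                                       basename(outputs)))),
                extra)
  jsonlite::write_json(manifest,
                       file.path(run_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

.require_upstream <- function(run_dir, file, needed_stage) {
  if (!file.exists(file.path(run_dir, file))) {
    stop(sprintf("missing upstream artifact %s: run stage '%s' first",
                 file, needed_stage))
  }
}

.past_periods <- c("mid_holocene", "lgm")

#' Run one pipeline stage
#'
#' Executes a stage of the end-to-end analysis, writing its outputs
#' (plain-text rasters, CSV tables, JSON manifests; fitted model bundles
#' as RDS) under `run_dir`. Stages depend on the outputs of earlier
#' stages and error with the name of the stage to run first when one is
#' missing. Deterministic stages are bit-identical on rerun.
#'
#' @param config a `run_config`.
#' @param stage one of `"simulate"`, `"select-vars"`, `"fit"`,
#'   `"project"`, `"cradles"`, `"survive"`, `"report"`.
#' @param run_dir run directory (created if needed).
#' @return the stage's principal result, invisibly (see details of each
#'   stage); every stage also writes a `manifest_<stage>.json`.
#' @export
run_stage <- function(config, stage, run_dir) {
  stopifnot(inherits(config, "run_config"))
  stage <- match.arg(stage, .pipeline_stages)
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  switch(stage,
         "simulate" = .stage_simulate(config, run_dir),
         "select-vars" = .stage_select_vars(config, run_dir),
         "fit" = .stage_fit(config, run_dir),
         "project" = .stage_project(config, run_dir),
         "cradles" = .stage_cradles(config, run_dir),
         "survive" = .stage_survive(config, run_dir),
         "report" = .stage_report(config, run_dir))
}

.stage_simulate <- function(config, run_dir) {
  sc <- config$scenario
  outputs <- character()
  stacks <- list(current_observed = simulate_stack(sc, "current", "observed"))
  for (p in .past_periods) {
    for (g in sc$gcms) {
      stacks[[paste(p, g, sep = "_")]] <- simulate_stack(sc, p, g)
    }
  }
  for (nm in names(stacks)) {
    d <- .stage_dir(run_dir, "stacks", nm)
    .stack_dir_write(stacks[[nm]], d)
    outputs <- c(outputs, list.files(d, full.names = TRUE))
  }
  soil <- make_soil_mask(sc)
  soil_path <- file.path(run_dir, "soil.asc")
  write_raster(soil, soil_path)
  occ_dir <- .stage_dir(run_dir, "occurrences")
  for (tx in names(config$taxa)) {
    tr <- true_suitability(config$taxa[[tx]], stacks$current_observed)
    occ <- sample_presences(tr, config$n_presences,
                            derive_seed(sc$seeds$presence, tx), taxon = tx)
    write_occurrences(occ, file.path(occ_dir, paste0(tx, ".csv")))
  }
  outputs <- c(outputs, soil_path, list.files(occ_dir, full.names = TRUE))
  meta <- list(seeds = sc$seeds, n_presences = config$n_presences,
               gcms = sc$gcms, variables = names(sc$variables),
               taxa = lapply(config$taxa, function(t) {
                 list(optimum = as.list(t$optimum),
                      breadth = as.list(t$breadth),
                      prevalence = t$prevalence)
               }))
  jsonlite::write_json(meta, file.path(run_dir, "scenario_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .write_manifest(run_dir, "simulate",
                  c(outputs, file.path(run_dir, "scenario_metadata.json")),
                  list(seed = config$seed))
  invisible(stacks)
}

.read_current_stack <- function(run_dir) {
  .require_upstream(run_dir, "stacks/current_observed", "simulate")
  .stack_dir_read(file.path(run_dir, "stacks", "current_observed"),
                  "current", "observed")
}

.read_occ <- function(run_dir, taxon) {
  f <- file.path(run_dir, "occurrences", paste0(taxon, ".csv"))
  .require_upstream(run_dir, file.path("occurrences", paste0(taxon, ".csv")),
                    "simulate")
  read_occurrences(f)
}

.stage_select_vars <- function(config, run_dir) {
  stack <- .read_current_stack(run_dir)
  occ <- thin_occurrences(.read_occ(run_dir, config$parents[1]), stack$grid)
  corr <- correlation_report(stack, seed = derive_seed(config$seed, "corr"))
  bg <- sample_background(stack,
                          max(config$background_multiplier * n_occurrences(occ),
                              config$background_min),
                          derive_seed(config$seed, "jack_bg"), exclude = occ)
  jack <- jackknife_contribution(occ, bg, stack, algorithm = "glm",
                                 seed = derive_seed(config$seed, "jack"))
  selected <- select_variables(corr, jack, forced = config$forced_variables)
  utils::write.csv(as.data.frame(corr$r),
                   file.path(run_dir, "correlation_matrix.csv"))
  merge_tab <- data.frame(step = seq_len(nrow(corr$linkage$merge)),
                          merge1 = corr$linkage$merge[, 1],
                          merge2 = corr$linkage$merge[, 2],
                          height = corr$linkage$height)
  utils::write.csv(merge_tab, file.path(run_dir, "dendrogram_merges.csv"),
                   row.names = FALSE)
  utils::write.csv(jack, file.path(run_dir, "jackknife.csv"),
                   row.names = FALSE)
  writeLines(selected, file.path(run_dir, "selected_variables.txt"))
  .write_manifest(run_dir, "select-vars",
                  file.path(run_dir, c("correlation_matrix.csv",
                                       "dendrogram_merges.csv",
                                       "jackknife.csv",
                                       "selected_variables.txt")))
  invisible(selected)
}

.selected_vars <- function(config, run_dir, stack) {
  if (!config$select_variables) return(stack_variables(stack))
  f <- file.path(run_dir, "selected_variables.txt")
  if (!file.exists(f)) return(stack_variables(stack))
  readLines(f)
}

.stage_fit <- function(config, run_dir) {
  stack <- .read_current_stack(run_dir)
  vars <- .selected_vars(config, run_dir, stack)
  stack <- stack_subset(stack, vars)
  model_dir <- .stage_dir(run_dir, "models")
  ev_all <- list()
  for (tx in c(config$parents, config$hybrid)) {
    occ <- thin_occurrences(.read_occ(run_dir, tx), stack$grid)
    bg <- sample_background(stack,
                            max(config$background_multiplier * n_occurrences(occ),
                                config$background_min),
                            derive_seed(config$seed, paste("bg", tx)),
                            exclude = occ)
    table <- training_table(stack, occ, bg)
    ens <- fit_ensemble(table, algorithms = config$algorithms,
                        n_replicates = config$n_replicates,
                        seed = derive_seed(config$seed, paste("fit", tx)),
                        weight_metric = config$weight_metric)
    saveRDS(ens, file.path(model_dir, paste0(tx, ".rds")))
    e <- ensemble_evaluation(ens)
    e$taxon <- tx
    ev_all[[tx]] <- e
  }
  ev <- do.call(rbind, ev_all)[, c("taxon", "algorithm", "auc", "tss")]
  rownames(ev) <- NULL
  utils::write.csv(ev, file.path(run_dir, "evaluation.csv"),
                   row.names = FALSE)
  .write_manifest(run_dir, "fit", file.path(run_dir, "evaluation.csv"),
                  list(variables = vars))
  invisible(ev)
}

.stage_project <- function(config, run_dir) {
  .require_upstream(run_dir, "models", "fit")
  sc <- config$scenario
  outputs <- character()
  for (tx in c(config$parents, config$hybrid)) {
    ens <- readRDS(file.path(run_dir, "models", paste0(tx, ".rds")))
    d <- .stage_dir(run_dir, "suitability", tx)
    cur <- project(ens, stack_subset(.read_current_stack(run_dir),
                                     ens$variables))
    write_raster(cur$mean, file.path(d, "current_mean.asc"))
    write_raster(cur$sd, file.path(d, "current_sd.asc"))
    for (p in .past_periods) {
      per_gcm <- lapply(sc$gcms, function(g) {
        st <- .stack_dir_read(file.path(run_dir, "stacks",
                                        paste(p, g, sep = "_")), p, g)
        project(ens, stack_subset(st, ens$variables))
      })
      cons <- gcm_consensus(per_gcm)
      write_raster(cons$mean, file.path(d, paste0(p, "_mean.asc")))
      write_raster(cons$sd, file.path(d, paste0(p, "_sd.asc")))
    }
    outputs <- c(outputs, list.files(d, full.names = TRUE))
  }
  .write_manifest(run_dir, "project", outputs)
  invisible(outputs)
}

.stage_cradles <- function(config, run_dir) {
  .require_upstream(run_dir, "suitability", "project")
  grid_stack <- .read_current_stack(run_dir)
  soil <- read_raster(file.path(run_dir, "soil.asc"))
  summaries <- lapply(config$parents, function(tx) {
    cur <- read_raster(file.path(run_dir, "suitability", tx,
                                 "current_mean.asc"))
    occ <- thin_occurrences(.read_occ(run_dir, tx), grid_stack$grid)
    suitability_summary(cur, occ)
  })
  interval <- if (config$interval_rule == "combined") {
    combined_interval(summaries[[1]], summaries[[2]])
  } else union_interval(summaries[[1]], summaries[[2]])
  int_tab <- data.frame(
    taxon = c(vapply(summaries, function(s) s$taxon, ""), "interval"),
    min = c(vapply(summaries, function(s) s$min, 0), interval$lower),
    q1 = c(vapply(summaries, function(s) s$q1, 0), interval$upper),
    rule = c("", "", interval$rule))
  utils::write.csv(int_tab, file.path(run_dir, "interval_report.csv"),
                   row.names = FALSE)
  outputs <- file.path(run_dir, "interval_report.csv")
  for (p in .past_periods) {
    maps <- lapply(config$parents, function(tx) {
      read_raster(file.path(run_dir, "suitability", tx,
                            paste0(p, "_mean.asc")))
    })
    ov <- overlap_mask(lsa_mask(maps[[1]], interval),
                       lsa_mask(maps[[2]], interval))
    cm <- soil_filter(ov, soil, period = p,
                      provenance = list(interval = interval))
    write_raster(cm$mask, file.path(run_dir, paste0("cradles_", p, ".asc")))
    utils::write.csv(cm$cells,
                     file.path(run_dir, paste0("cradles_", p, ".csv")),
                     row.names = FALSE)
    cf_log("cradles (%s): %d cell(s)", p, n_cradles(cm))
    outputs <- c(outputs, file.path(run_dir, paste0("cradles_", p,
                                                    c(".asc", ".csv"))))
  }
  .write_manifest(run_dir, "cradles", outputs,
                  list(interval = list(lower = interval$lower,
                                       upper = interval$upper,
                                       rule = interval$rule)))
  invisible(interval)
}

.stage_survive <- function(config, run_dir) {
  .require_upstream(run_dir, "cradles_lgm.asc", "cradles")
  hy <- config$hybrid
  grid_stack <- .read_current_stack(run_dir)
  hybrid_maps <- stats::setNames(lapply(
    c("current", .past_periods), function(p) {
      read_raster(file.path(run_dir, "suitability", hy,
                            paste0(p, "_mean.asc")))
    }), c("current", .past_periods))
  occ <- thin_occurrences(.read_occ(run_dir, hy), grid_stack$grid)
  thr <- survival_threshold(hybrid_maps$current, occ,
                            mode = config$threshold_mode)
  outputs <- character()
  expected <- list()
  for (p in .past_periods) {
    cm <- cradle_map(read_raster(file.path(run_dir,
                                           paste0("cradles_", p, ".asc"))),
                     period = p)
    traj <- evaluate_trajectory(cm, hybrid_maps, thr)
    utils::write.csv(traj$cells,
                     file.path(run_dir, paste0("trajectory_", p, ".csv")),
                     row.names = FALSE)
    surv <- surviving_cradles(traj, "current")
    expected[[p]] <- surv
    write_raster(surv$mask,
                 file.path(run_dir, paste0("surviving_", p, ".asc")))
    outputs <- c(outputs, file.path(run_dir, paste0("trajectory_", p, ".csv")),
                 file.path(run_dir, paste0("surviving_", p, ".asc")))
  }
  # expected current distribution: union of survivors from both origins
  exp_mask <- raster_new(grid_stack$grid,
                         pmin(expected$mid_holocene$mask$values +
                                expected$lgm$mask$values, 1))
  write_raster(exp_mask, file.path(run_dir, "expected_current.asc"))
  cov <- compare_with_occurrences(cradle_map(exp_mask, "current"), occ,
                                  radius_cells = 1)
  jsonlite::write_json(
    c(list(threshold_mode = thr$mode, threshold_value = thr$value), cov),
    file.path(run_dir, "coverage.json"), auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, file.path(run_dir, c("expected_current.asc",
                                             "coverage.json")))
  .write_manifest(run_dir, "survive", outputs,
                  list(threshold = thr$value, mode = thr$mode))
  invisible(cov)
}

.stage_report <- function(config, run_dir) {
  .require_upstream(run_dir, "coverage.json", "survive")
  interval <- utils::read.csv(file.path(run_dir, "interval_report.csv"))
  evaluation <- utils::read.csv(file.path(run_dir, "evaluation.csv"))
  coverage <- jsonlite::read_json(file.path(run_dir, "coverage.json"),
                                  simplifyVector = TRUE)
  counts <- lapply(stats::setNames(.past_periods, .past_periods),
                   function(p) {
    cm <- utils::read.csv(file.path(run_dir, paste0("cradles_", p, ".csv")))
    surv <- utils::read.csv(file.path(run_dir,
                                      paste0("trajectory_", p, ".csv")))
    list(cradles = nrow(cm),
         surviving_to_current = if (nrow(surv)) sum(surv$survived) else 0L)
  })
  report <- list(interval = interval, evaluation = evaluation,
                 cradle_counts = counts, coverage = coverage)
  jsonlite::write_json(report, file.path(run_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  txt <- c(
    "cradle-location pipeline report",
    sprintf("low-suitability interval (%s rule): [%.5g, %.5g]",
            interval$rule[nrow(interval)], interval$min[nrow(interval)],
            interval$q1[nrow(interval)]),
    sprintf("survival threshold (%s): %.5g", coverage$threshold_mode,
            coverage$threshold_value),
    sprintf("cradles at LGM: %d (%d survive to current)",
            counts$lgm$cradles, counts$lgm$surviving_to_current),
    sprintf("cradles at Mid-Holocene: %d (%d survive to current)",
            counts$mid_holocene$cradles,
            counts$mid_holocene$surviving_to_current),
    sprintf("occurrence cells covered by expected distribution (radius %d): %.3f",
            coverage$radius_cells, coverage$fraction_covered))
  writeLines(txt, file.path(run_dir, "report.txt"))
  .write_manifest(run_dir, "report",
                  file.path(run_dir, c("report.json", "report.txt")))
  invisible(report)
}
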