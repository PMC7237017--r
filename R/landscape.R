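#' Define a virtual taxon with a known Gaussian niche
#'
#' The taxon's true suitability at a cell is the product over predictor
#' variables of Gaussian kernels `exp(-(x - mu)^2 / (2 sigma^2))`, scaled
#' by a prevalence factor `c` in (0, 1]. Unimodal, separable responses
#' are the simplest form whose range geometry (core + low-suitability
#' margin) matches the allopatric-with-margin setting the cradle
#' hypothesis assumes.
#'
#' @param name taxon name.
#' @param optimum named numeric vector: per-variable niche optimum
#'   `mu_v`, in the variable's units.
#' @param breadth named numeric vector (same names): niche breadth
#'   `sigma_v > 0`.
#' @param prevalence scaler `c` in (0, 1]; true suitability at the joint
#'   optimum.
#' @return an object of class `virtual_taxon`.
#' @export
virtual_taxon <- function(name, optimum, breadth, prevalence = 1) {
  stopifnot(is.character(name), length(optimum) == length(breadth),
            setequal(names(optimum), names(breadth)),
            all(breadth > 0), prevalence > 0, prevalence <= 1)
  structure(list(name = name, optimum = optimum,
                 breadth = breadth[names(optimum)],
                 prevalence = prevalence),
            class = "virtual_taxon")
}

# Spatially autocorrelated Gaussian field on the grid: seeded white
# noise smoothed by FFT convolution with a Gaussian kernel (periodic
# boundary), rescaled to the requested marginal standard deviation.
gaussian_random_field <- function(n_rows, n_cols, corr_length, sd, seed) {
  if (sd <= 0) return(matrix(0, n_rows, n_cols))
  noise <- with_seed(seed, matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols))
  if (corr_length <= 0) return(noise * sd)
  dr <- pmin(0:(n_rows - 1), n_rows - 0:(n_rows - 1))
  dc <- pmin(0:(n_cols - 1), n_cols - 0:(n_cols - 1))
  kern <- exp(-outer(dr^2, dc^2, `+`) / (2 * corr_length^2))
  sm <- Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE)) /
    (n_rows * n_cols)
  sm * (sd / stats::sd(as.vector(sm)))
}

#' Configure a synthetic landscape scenario
#'
#' Describes everything needed to generate predictor stacks for all
#' periods and GCMs, a patchy soil mask, and (with [virtual_taxon()]
#' definitions) presence samples — all reproducible from the named seeds.
#' Each predictor layer is a deterministic linear gradient plus a seeded
#' spatially autocorrelated Gaussian field; past periods add a
#' per-variable shift, and each pseudo-GCM perturbs that shift with an
#' independent seeded jitter (emulating circulation models that disagree
#' about the same past climate).
#'
#' @param grid a `grid_spec`.
#' @param variables named list; each element a list with `base` (value at
#'   the north-west corner), `grad_lon`, `grad_lat` (total change west to
#'   east / north to south), `field_sd` (random-field standard
#'   deviation), `corr_length` (field correlation length, cells).
#' @param period_shifts named list (`mid_holocene`, `lgm`) of named
#'   numeric vectors: additive shift per variable.
#' @param gcms character vector of pseudo-GCM labels for past periods.
#' @param gcm_jitter_sd named numeric vector: standard deviation of the
#'   per-GCM jitter added to each variable's period shift.
#' @param soil list with `n_patches` and `mean_radius` (cells) for the
#'   gypsum-soil mask generator.
#' @param seeds named integer seeds (`field`, `gcm`, `soil`, `presence`);
#'   every stochastic step derives its stream from these.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(grid, variables, period_shifts, gcms,
                            gcm_jitter_sd, soil, seeds) {
  stopifnot(inherits(grid, "grid_spec"), length(variables) >= 1L,
            !is.null(names(variables)),
            all(c("field", "gcm", "soil", "presence") %in% names(seeds)),
            all(vapply(variables, function(v) v$field_sd, 0) >= 0),
            all(gcm_jitter_sd >= 0), soil$n_patches >= 1)
  structure(list(grid = grid, variables = variables,
                 period_shifts = period_shifts, gcms = gcms,
                 gcm_jitter_sd = gcm_jitter_sd, soil = soil, seeds = seeds),
            class = "scenario_config")
}

#' Default desk-scale scenario
#'
#' A 120 x 150 cell landscape (roughly Iberian extent at 5 arc-minute
#' cells) with four bioclim-style variables: temperature seasonality
#' (`tseas`), minimum temperature of the coldest month (`tmin`),
#' precipitation of the wettest month (`pwet`) and of the driest month
#' (`pdry`). Gradients run mainly west-to-east (continentality, summer
#' drought) and north-to-south (winter temperature, overall rainfall).
#' The LGM shift is colder and drier with higher seasonality; the
#' Mid-Holocene is intermediate. Three pseudo-GCMs jitter the past
#' shifts.
#'
#' @param seed base seed from which all named seeds are derived.
#' @return a `scenario_config`.
#' @export
default_scenario <- function(seed = 20200519) {
  grid <- grid_spec(120, 150, origin_lon = -9.5, origin_lat = 44,
                    cell_size = 1 / 12)
  variables <- list(
    tseas = list(base = 420, grad_lon = 260, grad_lat = 40,
                 field_sd = 35, corr_length = 10),
    tmin  = list(base = -25, grad_lon = 15, grad_lat = 95,
                 field_sd = 18, corr_length = 10),
    pwet  = list(base = 145, grad_lon = -55, grad_lat = -45,
                 field_sd = 14, corr_length = 8),
    pdry  = list(base = 48, grad_lon = -30, grad_lat = -12,
                 field_sd = 9, corr_length = 8))
  period_shifts <- list(
    mid_holocene = c(tseas = 21, tmin = -21, pwet = -5.25, pdry = -3),
    lgm          = c(tseas = 52.5, tmin = -52.5, pwet = -13.5, pdry = -7.5))
  scenario_config(
    grid = grid, variables = variables, period_shifts = period_shifts,
    gcms = c("gcmA", "gcmB", "gcmC"),
    gcm_jitter_sd = c(tseas = 9, tmin = 6, pwet = 3.75, pdry = 2.25),
    soil = list(n_patches = 35, mean_radius = 4),
    seeds = list(field = derive_seed(seed, "field"),
                 gcm = derive_seed(seed, "gcm"),
                 soil = derive_seed(seed, "soil"),
                 presence = derive_seed(seed, "presence")))
}

#' Default virtual taxa for the synthetic scenario
#'
#' Two parental taxa with partially overlapping niches displaced along
#' the continentality/summer-drought axes (allopatric cores, overlapping
#' margins) and an intermediate hybrid with a narrower niche.
#'
#' @return named list of three `virtual_taxon` objects
#'   (`parent_west`, `parent_east`, `hybrid`).
#' @export
default_taxa <- function() {
  list(
    parent_west = virtual_taxon(
      "parent_west",
      optimum = c(tseas = 530, tmin = 34, pwet = 110, pdry = 30),
      breadth = c(tseas = 30, tmin = 18.75, pwet = 16.5, pdry = 6.75)),
    parent_east = virtual_taxon(
      "parent_east",
      optimum = c(tseas = 600, tmin = 40, pwet = 96, pdry = 21),
      breadth = c(tseas = 30, tmin = 18.75, pwet = 16.5, pdry = 6.75)),
    hybrid = virtual_taxon(
      "hybrid",
      optimum = c(tseas = 565, tmin = 37, pwet = 103, pdry = 25),
      breadth = c(tseas = 24, tmin = 15, pwet = 13.5, pdry = 5.25)))
}

#' Generate a predictor stack for one period and GCM
#'
#' The base landscape (gradient + seeded random field per variable) is
#' identical across periods and GCMs — the same geography under
#' different climates — so projections onto past stacks are meaningful.
#' Past periods add the configured per-variable shift; each pseudo-GCM
#' adds an independent seeded jitter to that shift. The `"observed"` GCM
#' is only valid for the current period (shift and jitter zero).
#'
#' @param config a `scenario_config`.
#' @param period `"current"`, `"mid_holocene"` or `"lgm"`.
#' @param gcm GCM label from `config$gcms`, or `"observed"`.
#' @return a `predictor_stack`.
#' @export
simulate_stack <- function(config, period = "current", gcm = "observed") {
  stopifnot(inherits(config, "scenario_config"))
  period <- match.arg(period, c("current", "mid_holocene", "lgm"))
  if (period == "current") {
    if (!identical(gcm, "observed")) {
      stop("current-period stacks use gcm = \"observed\"")
    }
  } else {
    if (!gcm %in% config$gcms) stop("unknown gcm: ", gcm)
    if (!period %in% names(config$period_shifts)) {
      stop("no period shift configured for ", period)
    }
  }
  g <- config$grid
  lon_norm <- matrix((seq_len(g$n_cols) - 0.5) / g$n_cols,
                     g$n_rows, g$n_cols, byrow = TRUE)
  lat_norm <- matrix((seq_len(g$n_rows) - 0.5) / g$n_rows,
                     g$n_rows, g$n_cols)
  layers <- list()
  for (v in names(config$variables)) {
    spec <- config$variables[[v]]
    base <- spec$base + spec$grad_lon * lon_norm + spec$grad_lat * lat_norm
    field <- gaussian_random_field(g$n_rows, g$n_cols, spec$corr_length,
                                   spec$field_sd,
                                   derive_seed(config$seeds$field, v))
    shift <- 0
    if (period != "current") {
      shift <- config$period_shifts[[period]][[v]]
      jsd <- config$gcm_jitter_sd[[v]]
      if (jsd > 0) {
        shift <- shift + with_seed(
          derive_seed(config$seeds$gcm, paste(period, gcm, v)),
          stats::rnorm(1, 0, jsd))
      }
    }
    layers[[v]] <- raster_new(g, base + field + shift)
  }
  predictor_stack(layers, period = period, gcm = gcm)
}

#' True suitability of a virtual taxon on a stack
#'
#' Cellwise product of the per-variable Gaussian kernels times the
#' prevalence scaler; the ground truth every fitted model is judged
#' against. Nodata propagates.
#'
#' @param taxon a `virtual_taxon` defining a response for every stack
#'   layer.
#' @param stack a `predictor_stack`.
#' @return a `cf_raster` with values in \[0, 1\].
#' @export
true_suitability <- function(taxon, stack) {
  stopifnot(inherits(taxon, "virtual_taxon"),
            inherits(stack, "predictor_stack"))
  missing <- setdiff(names(stack$layers), names(taxon$optimum))
  if (length(missing)) {
    stop("taxon ", taxon$name, " has no response for: ",
         paste(missing, collapse = ", "))
  }
  g <- stack$grid
  s <- matrix(taxon$prevalence, g$n_rows, g$n_cols)
  for (v in names(stack$layers)) {
    x <- stack$layers[[v]]$values
    s <- s * exp(-(x - taxon$optimum[[v]])^2 / (2 * taxon$breadth[[v]]^2))
  }
  raster_new(g, s)
}

#' Sample presence points proportional to true suitability
#'
#' Draws `n` distinct cells without replacement with probability
#' proportional to suitability and returns their centers — one record
#' per cell, i.e. the post-thinning world the models see.
#'
#' @param true_r a `cf_raster` of true suitability.
#' @param n number of presences.
#' @param seed integer seed.
#' @param taxon name for the resulting `occurrence_set`.
#' @return an `occurrence_set` of `n` cell centers.
#' @export
sample_presences <- function(true_r, n, seed, taxon = "virtual") {
  stopifnot(inherits(true_r, "cf_raster"), n >= 1)
  v <- true_r$values
  eligible <- which(!is.na(v) & v > 0)
  if (length(eligible) < n) {
    stop(sprintf("only %d cell(s) with positive suitability, need %d",
                 length(eligible), n))
  }
  picked <- with_seed(seed,
                      sample(eligible, n, replace = FALSE, prob = v[eligible]))
  row <- (picked - 1L) %% nrow(v)        # column-major index -> (row, col)
  col <- (picked - 1L) %/% nrow(v)
  ctr <- cell_center(true_r$grid, row, col)
  occurrence_set(taxon, ctr$lon, ctr$lat)
}

#' Generate a patchy binary soil mask
#'
#' Union of seeded circular patches (Euclidean distance in cell units),
#' emulating a digitized map of scattered gypsum outcrops. Patch centers
#' are uniform over the grid; each radius is uniform in
#' `[0.5, 1.5] * mean_radius`.
#'
#' @param config a `scenario_config` (uses `config$soil` and
#'   `config$seeds$soil`).
#' @return a binary `cf_raster` (values 0/1); the covered fraction is
#'   reported in the log and as attribute `fraction`.
#' @export
make_soil_mask <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  g <- config$grid
  np <- config$soil$n_patches
  mr <- config$soil$mean_radius
  dat <- with_seed(config$seeds$soil, list(
    row = stats::runif(np, 0, g$n_rows), col = stats::runif(np, 0, g$n_cols),
    radius = stats::runif(np, 0.5, 1.5) * mr))
  rows <- matrix(seq_len(g$n_rows) - 0.5, g$n_rows, g$n_cols)
  cols <- matrix(seq_len(g$n_cols) - 0.5, g$n_rows, g$n_cols, byrow = TRUE)
  m <- matrix(0, g$n_rows, g$n_cols)
  for (i in seq_len(np)) {
    m[(rows - dat$row[i])^2 + (cols - dat$col[i])^2 <= dat$radius[i]^2] <- 1
  }
  out <- raster_new(g, m)
  frac <- mean(m)
  attr(out, "fraction") <- frac
  cf_log("soil mask: %d patches, %.1f%% of grid covered", np, 100 * frac)
  out
}

#' Ground-truth cradles from true suitabilities
#'
#' Applies the cradle definition — both parents' suitability inside the
#' low-suitability band, on suitable soil — to the TRUE suitability
#' surfaces, giving the oracle against which fitted cradles are scored.
#'
#' @param parent_a,parent_b `virtual_taxon` objects.
#' @param stack the `predictor_stack` (period) on which to evaluate.
#' @param soil binary `cf_raster` soil mask.
#' @param band an `lsa_interval` (see [combined_interval()]), computed
#'   from true suitabilities at presence cells with the same rule the
#'   fitted pipeline uses.
#' @return a binary `cf_raster`: 1 where all three conditions hold.
#' @export
oracle_cradles <- function(parent_a, parent_b, stack, soil, band) {
  stopifnot(inherits(band, "lsa_interval"))
  sa <- true_suitability(parent_a, stack)$values
  sb <- true_suitability(parent_b, stack)$values
  m <- (sa >= band$lower & sa <= band$upper &
          sb >= band$lower & sb <= band$upper &
          soil$values == 1) * 1
  raster_new(stack$grid, m)
}
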