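# Shared fixtures: everything is generated in code, no files.

# a small grid: origin at (0, nr*cs) so the lat range is [0, nr*cs]
small_grid <- function(nr = 6, nc = 8, cs = 0.5) {
  grid_spec(nr, nc, origin_lon = 0, origin_lat = nr * cs, cell_size = cs)
}

# seeded random raster on a grid, values in [0, 1], optional nodata cells
random_raster <- function(grid, seed, nodata_frac = 0) {
  v <- cradlefinder:::with_seed(seed, {
    m <- matrix(stats::runif(grid$n_rows * grid$n_cols),
                grid$n_rows, grid$n_cols)
    if (nodata_frac > 0) {
      m[sample(length(m), round(nodata_frac * length(m)))] <- NA
    }
    m
  })
  raster_new(grid, v)
}

# seeded random binary mask
random_mask <- function(grid, seed, p = 0.5) {
  v <- cradlefinder:::with_seed(
    seed, matrix(stats::rbinom(grid$n_rows * grid$n_cols, 1, p),
                 grid$n_rows, grid$n_cols))
  raster_new(grid, v)
}

# scaled-down scenario for unit tests (fast): 40 x 50 cells
tiny_scenario <- function(seed = 42) {
  sc <- default_scenario(seed)
  sc$grid <- grid_spec(40, 50, origin_lon = -9.5, origin_lat = 44,
                       cell_size = 0.25)
  for (v in names(sc$variables)) sc$variables[[v]]$corr_length <- 4
  sc$soil <- list(n_patches = 12, mean_radius = 2.5)
  sc
}

# random points inside (or slightly outside) a grid's bounding box
random_points <- function(grid, n, seed, margin = 0) {
  cradlefinder:::with_seed(seed, {
    w <- grid$n_cols * grid$cell_size
    h <- grid$n_rows * grid$cell_size
    list(lon = runif(n, grid$origin_lon - margin * w,
                     grid$origin_lon + (1 + margin) * w),
         lat = runif(n, grid$origin_lat - (1 + margin) * h,
                     grid$origin_lat + margin * h))
  })
}

# brute-force point-in-cell containment: half-open [west,east)x(south,north]
brute_force_cell <- function(grid, lon, lat) {
  out <- data.frame(row = rep(NA_integer_, length(lon)),
                    col = rep(NA_integer_, length(lon)))
  for (i in seq_along(lon)) {
    for (r in seq_len(grid$n_rows) - 1L) {
      north <- grid$origin_lat - r * grid$cell_size
      south <- north - grid$cell_size
      if (!(lat[i] <= north && lat[i] > south)) next
      for (cc in seq_len(grid$n_cols) - 1L) {
        west <- grid$origin_lon + cc * grid$cell_size
        east <- west + grid$cell_size
        if (lon[i] >= west && lon[i] < east) {
          out$row[i] <- r
          out$col[i] <- cc
        }
      }
    }
  }
  out
}

# brute-force AUC by explicit pairwise enumeration, ties counted 1/2
brute_force_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# brute-force TSS by exhaustive threshold enumeration
brute_force_tss <- function(pos, neg) {
  best <- -Inf
  for (t in sort(unique(c(pos, neg)))) {
    sens <- sum(pos >= t) / length(pos)
    spec <- sum(neg < t) / length(neg)
    best <- max(best, sens + spec - 1)
  }
  best
}
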