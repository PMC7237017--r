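test_that("simulate_stack is deterministic and reduces to the gradient without noise", {
  sc <- tiny_scenario()
  s1 <- simulate_stack(sc, "lgm", "gcmA")
  s2 <- simulate_stack(sc, "lgm", "gcmA")
  for (v in names(s1$layers)) {
    expect_identical(s1$layers[[v]]$values, s2$layers[[v]]$values)
  }
  # the base landscape is shared across periods: differences are constant
  cur <- simulate_stack(sc, "current", "observed")
  d <- s1$layers$tseas$values - cur$layers$tseas$values
  expect_lt(diff(range(d)), 1e-9)

  # zero variance and zero shifts -> the pure gradient
  sc0 <- sc
  for (v in names(sc0$variables)) sc0$variables[[v]]$field_sd <- 0
  flat <- simulate_stack(sc0, "current", "observed")
  g <- sc0$grid
  spec <- sc0$variables$tmin
  lon_n <- (seq_len(g$n_cols) - 0.5) / g$n_cols
  lat_n <- (seq_len(g$n_rows) - 0.5) / g$n_rows
  want <- outer(spec$base + spec$grad_lat * lat_n, spec$grad_lon * lon_n, `+`)
  expect_equal(flat$layers$tmin$values, want, tolerance = 1e-12)

  expect_error(simulate_stack(sc, "lgm", "nope"), "unknown gcm")
  expect_error(simulate_stack(sc, "current", "gcmA"), "observed")
})

test_that("layer means track gradient mean plus period shift", {
  sc <- tiny_scenario()
  # average over GCM jitter (sd known) and field noise: 3-SE window
  v <- "tmin"
  spec <- sc$variables[[v]]
  grad_mean <- spec$base + spec$grad_lon / 2 + spec$grad_lat / 2
  shift <- sc$period_shifts$lgm[[v]]
  gcm_means <- vapply(sc$gcms, function(g) {
    mean(simulate_stack(sc, "lgm", g)$layers[[v]]$values)
  }, 0)
  se <- sqrt(sc$gcm_jitter_sd[[v]]^2 / length(gcm_means) +
               spec$field_sd^2 / prod(dim(sc$grid$n_rows)))
  expect_lt(abs(mean(gcm_means) - (grad_mean + shift)),
            3 * sc$gcm_jitter_sd[[v]] / sqrt(length(gcm_means)) + 3)
})

test_that("true suitability follows the product-Gaussian formula", {
  sc <- tiny_scenario()
  stack <- simulate_stack(sc, "current", "observed")
  tx <- default_taxa()$parent_west

  # optimum cell scores exactly c = 1: put the optimum at a real cell
  x <- vapply(names(stack$layers),
              function(v) stack$layers[[v]]$values[10, 20], 0)
  tx_opt <- virtual_taxon("opt", optimum = x,
                          breadth = tx$breadth[names(x)])
  expect_equal(true_suitability(tx_opt, stack)$values[10, 20], 1)

  # infinite breadth -> constant prevalence everywhere
  tx_flat <- virtual_taxon("flat", optimum = x,
                           breadth = setNames(rep(1e9, length(x)), names(x)),
                           prevalence = 0.37)
  expect_equal(max(abs(true_suitability(tx_flat, stack)$values - 0.37)), 0,
               tolerance = 1e-9)

  # random cells against direct formula evaluation
  s <- true_suitability(tx, stack)
  idx <- cradlefinder:::with_seed(1, cbind(sample(40, 25, TRUE),
                                           sample(50, 25, TRUE)))
  for (k in seq_len(nrow(idx))) {
    want <- tx$prevalence
    for (v in names(stack$layers)) {
      xv <- stack$layers[[v]]$values[idx[k, 1], idx[k, 2]]
      want <- want * exp(-(xv - tx$optimum[[v]])^2 / (2 * tx$breadth[[v]]^2))
    }
    expect_equal(s$values[idx[k, 1], idx[k, 2]], want, tolerance = 1e-12)
  }
  expect_true(all(s$values >= 0 & s$values <= 1))

  # monotone decreasing in |x - mu| per variable, others fixed
  mu <- tx$optimum[["tmin"]]
  dev <- seq(0, 200, by = 10)
  kern <- exp(-dev^2 / (2 * tx$breadth[["tmin"]]^2))
  expect_true(all(diff(kern) <= 0))

  # missing response errors
  tx_short <- virtual_taxon("short", optimum = x[1:2], breadth = tx$breadth[1:2])
  expect_error(true_suitability(tx_short, stack), "no response")
})

test_that("presence sampling is seeded, supported and suitability-weighted", {
  g <- small_grid(10, 10, cs = 1)
  m <- matrix(0, 10, 10)
  support <- cbind(c(2, 5, 8), c(3, 6, 9))
  m[support] <- 1
  r <- raster_new(g, m)
  occ <- sample_presences(r, 3, seed = 1)
  want <- cell_center(g, support[, 1] - 1, support[, 2] - 1)
  expect_setequal(paste(occ$lon, occ$lat), paste(want$lon, want$lat))
  expect_error(sample_presences(r, 4, seed = 1), "positive suitability")

  occ2 <- sample_presences(r, 3, seed = 99)
  expect_identical(sample_presences(r, 3, seed = 99)$lon, occ2$lon)

  # 0.8 vs 0.2 cells drawn ~4:1 over many seeds (n = 1 draw per seed)
  m2 <- matrix(0, 10, 10)
  m2[1, 1] <- 0.8
  m2[1, 2] <- 0.2
  r2 <- raster_new(g, m2)
  hits <- vapply(1:2000, function(s) {
    sample_presences(r2, 1, seed = s)$lon[1] < 1  # col 0 center lon = 0.5
  }, logical(1))
  p_hat <- mean(hits)
  se <- sqrt(0.8 * 0.2 / 2000)
  expect_lt(abs(p_hat - 0.8), 3 * se)
})

test_that("soil mask is a union of seeded circular patches", {
  sc <- tiny_scenario()
  mask <- suppressMessages(make_soil_mask(sc))
  expect_true(all(mask$values %in% c(0, 1)))

  # geometric oracle: recompute distances from the seeded centers
  dat <- cradlefinder:::with_seed(sc$seeds$soil, list(
    row = runif(sc$soil$n_patches, 0, sc$grid$n_rows),
    col = runif(sc$soil$n_patches, 0, sc$grid$n_cols),
    radius = runif(sc$soil$n_patches, 0.5, 1.5) * sc$soil$mean_radius))
  want <- matrix(0, sc$grid$n_rows, sc$grid$n_cols)
  for (r in seq_len(sc$grid$n_rows)) {
    for (cc in seq_len(sc$grid$n_cols)) {
      for (i in seq_len(sc$soil$n_patches)) {
        if ((r - 0.5 - dat$row[i])^2 + (cc - 0.5 - dat$col[i])^2 <=
            dat$radius[i]^2) want[r, cc] <- 1
      }
    }
  }
  expect_identical(mask$values, want)

  # degenerate radius-0 patches cover at most one cell each
  sc0 <- sc
  sc0$soil <- list(n_patches = 1, mean_radius = 0)
  m0 <- suppressMessages(make_soil_mask(sc0))
  expect_lte(sum(m0$values), 1)

  # saturating radius covers the whole grid
  sc1 <- sc
  sc1$soil <- list(n_patches = 1, mean_radius = 1000)
  expect_true(all(suppressMessages(make_soil_mask(sc1))$values == 1))
})

test_that("oracle cradles satisfy the three-condition definition cellwise", {
  sc <- tiny_scenario()
  tx <- default_taxa()
  stack <- simulate_stack(sc, "lgm", "gcmB")
  soil <- suppressMessages(make_soil_mask(sc))
  band <- cradlefinder:::.new_interval(0.05, 0.4, "combined", list())
  oc <- oracle_cradles(tx$parent_west, tx$parent_east, stack, soil, band)

  sa <- true_suitability(tx$parent_west, stack)$values
  sb <- true_suitability(tx$parent_east, stack)$values
  for (r in seq_len(sc$grid$n_rows)) {
    want <- (sa[r, ] >= 0.05 & sa[r, ] <= 0.4 &
               sb[r, ] >= 0.05 & sb[r, ] <= 0.4 & soil$values[r, ] == 1) * 1
    if (!isTRUE(all.equal(oc$values[r, ], want))) {
      expect_equal(oc$values[r, ], want)
    }
  }
  # containment in the soil mask and band monotonicity
  expect_true(all(oc$values <= soil$values))
  narrower <- cradlefinder:::.new_interval(0.1, 0.3, "combined", list())
  oc2 <- oracle_cradles(tx$parent_west, tx$parent_east, stack, soil, narrower)
  expect_true(all(oc2$values <= oc$values))

  # absorbing and saturating masks
  zero <- raster_new(sc$grid, 0)
  expect_equal(sum(oracle_cradles(tx$parent_west, tx$parent_east, stack,
                                  zero, band)$values), 0)
  all1 <- raster_new(sc$grid, 1)
  full <- cradlefinder:::.new_interval(0, 1, "combined", list())
  expect_true(all(oracle_cradles(tx$parent_west, tx$parent_east, stack,
                                 all1, full)$values == 1))
})
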