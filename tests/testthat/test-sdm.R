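# a small separable training table: presence iff x1 > 0
separable_table <- function(n = 120, seed = 1) {
  cradlefinder:::with_seed(seed, {
    x1 <- c(runif(n / 2, 0.5, 2), runif(n / 2, -2, -0.5))
    x2 <- runif(n)
    structure(list(predictors = data.frame(x1 = x1, x2 = x2),
                   label = rep(c(1, 0), each = n / 2),
                   provenance = list(taxon = "synthetic")),
              class = "training_table")
  })
}

test_that("background sampling is seeded, uniform and exclusion-aware", {
  sc <- tiny_scenario()
  stack <- simulate_stack(sc, "current", "observed")
  b1 <- sample_background(stack, 100, seed = 5)
  b2 <- sample_background(stack, 100, seed = 5)
  expect_identical(b1$lon, b2$lon)

  # forced support: a grid with exactly n eligible cells returns all
  g <- small_grid(3, 3, cs = 1)
  m <- matrix(NA_real_, 3, 3)
  m[1, ] <- 1
  tiny <- predictor_stack(list(v = raster_new(g, m)))
  got <- sample_background(tiny, 3, seed = 1)
  expect_setequal(got$lon, cell_center(g, c(0, 0, 0), 0:2)$lon)
  expect_error(sample_background(tiny, 4, seed = 1), "eligible")

  # presences are excluded
  pres <- occurrence_set("t", cell_center(g, 0, 0)$lon, cell_center(g, 0, 0)$lat)
  got2 <- sample_background(tiny, 2, seed = 1, exclude = pres)
  expect_false(any(got2$lon == pres$lon & got2$lat == pres$lat))

  # uniformity over seeds: each of the 3 cells drawn ~1/3 of the time
  cols <- vapply(1:1500, function(s) {
    sample_background(tiny, 1, seed = s)$lon
  }, 0)
  freq <- table(cols) / 1500
  expect_true(all(abs(freq - 1 / 3) < 3 * sqrt((1 / 3) * (2 / 3) / 1500)))
})

test_that("every algorithm fits, stays in [0,1], and is seed-deterministic", {
  tab <- separable_table()
  for (alg in sdm_algorithms()) {
    m1 <- fit_replicate(alg, tab, replicate_seed = 10)
    m2 <- fit_replicate(alg, tab, replicate_seed = 10)
    p1 <- predict_replicate(m1, tab$predictors)
    p2 <- predict_replicate(m2, tab$predictors)
    expect_identical(p1, p2)
    expect_true(all(p1 >= 0 & p1 <= 1))
    expect_identical(m1$inbag, m2$inbag)
  }
})

test_that("a GLM separates linearly separable data almost perfectly", {
  tab <- separable_table()
  m <- suppressMessages(fit_replicate("glm", tab, replicate_seed = 3))
  p <- predict_replicate(m, tab$predictors)
  expect_gte(auc_score(p[tab$label == 1], p[tab$label == 0]), 0.99)
})

test_that("uninformative data yields near-chance predictions for all algorithms", {
  # identical predictor rows under both labels
  df <- data.frame(x1 = rep(0.5, 200), x2 = rep(1.2, 200))
  tab <- structure(list(predictors = df, label = rep(c(1, 0), 100),
                        provenance = list(taxon = "flat")),
                   class = "training_table")
  for (alg in sdm_algorithms()) {
    m <- suppressMessages(fit_replicate(alg, tab, replicate_seed = 4))
    p <- predict_replicate(m, tab$predictors)
    expect_true(all(p >= 0.4 & p <= 0.6),
                info = paste(alg, "predicted outside [0.4, 0.6]"))
  }
})

test_that("evaluate scores out-of-bag and falls back to the full table", {
  tab <- separable_table()
  m <- suppressMessages(fit_replicate("glm", tab, replicate_seed = 6))
  expect_equal(m$metrics$eval_on, "oob")
  expect_true(m$metrics$auc >= 0 && m$metrics$auc <= 1)
  # force an empty out-of-bag set
  m2 <- m
  m2$oob <- integer(0)
  got <- suppressMessages(evaluate(m2, tab))
  expect_equal(got$eval_on, "full")
})

test_that("weighted ensembles average members cellwise", {
  g <- small_grid(4, 5, cs = 1)
  a <- raster_new(g, 0.2)
  b <- raster_new(g, 0.6)
  ens <- weighted_ensemble(list(a, b), weights = c(1, 3))
  expect_equal(unique(as.vector(ens$mean$values)), 0.5)

  # identical members agree exactly: sd = 0
  ens2 <- weighted_ensemble(list(a, a, a))
  expect_equal(ens2$mean$values, a$values)
  expect_true(all(ens2$sd$values == 0))

  # formula oracle on random members and weights
  members <- lapply(1:4, function(i) random_raster(g, seed = 30 + i))
  w <- c(0.5, 2, 1, 0.25)
  ens3 <- weighted_ensemble(members, w)
  for (r in 1:4) for (cc in 1:5) {
    x <- vapply(members, function(m) m$values[r, cc], 0)
    mu <- sum(w * x) / sum(w)
    expect_equal(ens3$mean$values[r, cc], mu, tolerance = 1e-12)
    expect_equal(ens3$sd$values[r, cc],
                 sqrt(sum(w * (x - mu)^2) / sum(w)), tolerance = 1e-12)
  }
  # bounded by member min/max cellwise
  lo <- Reduce(pmin, lapply(members, function(m) m$values))
  hi <- Reduce(pmax, lapply(members, function(m) m$values))
  expect_true(all(ens3$mean$values >= lo - 1e-12 &
                    ens3$mean$values <= hi + 1e-12))
  expect_error(weighted_ensemble(list(a, random_raster(small_grid(3, 3), 1))),
               "grid mismatch")
})

test_that("projection reproduces the training ensemble and propagates nodata", {
  sc <- tiny_scenario()
  stack <- simulate_stack(sc, "current", "observed")
  tx <- default_taxa()$parent_west
  tr <- true_suitability(tx, stack)
  occ <- sample_presences(tr, 80, seed = 1, taxon = "w")
  bg <- sample_background(stack, 400, seed = 2, exclude = occ)
  tab <- training_table(stack, occ, bg)
  ens <- suppressMessages(fit_ensemble(tab, algorithms = c("glm", "maxent"),
                                       n_replicates = 3, seed = 7))
  p1 <- project(ens, stack)
  p2 <- project(ens, stack)
  expect_identical(p1$mean$values, p2$mean$values)
  expect_equal(p1$period, "current")

  # nodata cells in the projection stack yield nodata predictions
  stack_na <- stack
  stack_na$layers$tmin$values[3, 4] <- NA
  p3 <- project(ens, stack_na)
  expect_true(is.na(p3$mean$values[3, 4]))
  expect_false(is.na(p3$mean$values[1, 1]))

  # missing variable is named in the error
  expect_error(project(ens, stack_subset(stack, c("tseas", "pwet", "pdry"))),
               "tmin")
})

test_that("a monotone single-variable member shifts suitability monotonically", {
  g <- small_grid(8, 8, cs = 1)
  grad <- matrix(seq(0, 1, length.out = 64), 8, 8)
  stack <- predictor_stack(list(x = raster_new(g, grad)))
  # a strictly monotone logistic member (increasing in x)
  df <- data.frame(x = runif(200), stringsAsFactors = FALSE)
  df$.cf_label <- cradlefinder:::with_seed(
    1, rbinom(200, 1, plogis(8 * (df$x - 0.5))))
  lin <- stats::glm(.cf_label ~ x, family = binomial(), data = df)
  member <- structure(list(
    algorithm = "glm", seed = 1,
    fit = structure(list(algorithm = "glm", fit = lin, vars = "x"),
                    class = "cf_sdm_fit"),
    inbag = 1:200, oob = integer(0),
    metrics = list(auc = 1, tss = 1, tss_threshold = 0.5)),
    class = "model_replicate")
  ens <- structure(list(members = list(member), weights = 1,
                        variables = "x", taxon = "mono",
                        evaluation = data.frame()),
                   class = "sdm_ensemble")
  base <- project(ens, stack)
  shifted_stack <- predictor_stack(list(x = raster_new(g, grad - 0.3)))
  shifted <- project(ens, shifted_stack)
  d <- shifted$mean$values - base$mean$values
  expect_true(all(d < 0))   # lower x everywhere -> lower suitability
})

test_that("GCM consensus is the unweighted mean with SD uncertainty", {
  g <- small_grid(4, 4, cs = 1)
  mk <- function(seed) {
    structure(list(mean = random_raster(g, seed), sd = raster_new(g, 0),
                   weights = 1, period = "lgm", gcm = paste0("g", seed)),
              class = "ensemble_prediction")
  }
  one <- gcm_consensus(list(mk(1)))
  expect_equal(one$mean$values, random_raster(g, 1)$values)
  expect_true(all(one$sd$values == 0))

  same <- gcm_consensus(list(mk(2), mk(2), mk(2)))
  expect_true(all(same$sd$values == 0))

  preds <- list(mk(3), mk(4), mk(5))
  cons <- gcm_consensus(preds)
  vals <- lapply(preds, function(p) p$mean$values)
  mu <- Reduce(`+`, vals) / 3
  expect_equal(cons$mean$values, mu, tolerance = 1e-12)
  sd_want <- sqrt(Reduce(`+`, lapply(vals, function(v) (v - mu)^2)) / 3)
  expect_equal(cons$sd$values, sd_want, tolerance = 1e-12)

  bad <- mk(6)
  bad$period <- "mid_holocene"
  expect_error(gcm_consensus(list(mk(1), bad)), "mix periods")
})
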