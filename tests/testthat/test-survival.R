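# build a cradle_map from explicit (row, col) cells
mk_cradles <- function(grid, rows, cols, period = "lgm") {
  m <- matrix(0, grid$n_rows, grid$n_cols)
  m[cbind(rows + 1L, cols + 1L)] <- 1
  cradle_map(raster_new(grid, m), period = period)
}

mk_threshold <- function(value, mode = "min") {
  s <- new_suitability_summary("hybrid", min = value,
                               q1 = min(1, value + 0.1))
  structure(list(mode = mode, value = value, summary = s),
            class = "survival_threshold")
}

test_that("survival thresholds follow the min / q1 / mid modes", {
  g <- small_grid(2, 2, cs = 1)
  r <- raster_new(g, matrix(c(0.3, 0.5, 0.7, 0.9), 2))
  ctr <- cell_center(g, c(0, 1, 0, 1), c(0, 0, 1, 1))
  occ <- occurrence_set("hy", ctr$lon, ctr$lat)
  expect_equal(survival_threshold(r, occ, "min")$value, 0.3)

  s <- new_suitability_summary("hy", values = c(0.2, 0.4, 0.6, 0.8))
  expect_equal(threshold_from_summary(s, "q1")$value, 0.35)
  expect_equal(threshold_from_summary(s, "mid")$value, 0.275)

  # degenerate constant readings: all modes agree
  s2 <- new_suitability_summary("hy", values = rep(0.5, 5))
  for (m in c("min", "q1", "mid")) {
    expect_equal(threshold_from_summary(s2, m)$value, 0.5)
  }
  # ordering invariant: min <= mid <= q1
  expect_lte(threshold_from_summary(s, "min")$value,
             threshold_from_summary(s, "mid")$value)
  expect_lte(threshold_from_summary(s, "mid")$value,
             threshold_from_summary(s, "q1")$value)
})

test_that("trajectories apply sequential survival at >= threshold", {
  g <- small_grid(4, 4, cs = 1)
  cr <- mk_cradles(g, c(0, 1, 2), c(0, 1, 2), period = "lgm")
  mh <- raster_new(g, 0.5)
  cur <- raster_new(g, 0.5)

  # threshold 0 is vacuous
  t0 <- evaluate_trajectory(cr, list(mid_holocene = mh, current = cur),
                            mk_threshold(0))
  expect_true(all(t0$cells$survived))

  # suitability exactly at the threshold survives (>=)
  texact <- evaluate_trajectory(cr, list(mid_holocene = mh, current = cur),
                                mk_threshold(0.5))
  expect_true(all(texact$cells$survived))

  # hybrid collapse at MH dooms every LGM cradle whatever current says
  tmh <- evaluate_trajectory(cr, list(mid_holocene = raster_new(g, 0),
                                      current = raster_new(g, 1)),
                             mk_threshold(0.2))
  expect_false(any(tmh$cells$survived))
  expect_false(any(tmh$cells$survived_current))

  # MH-origin cradles are only judged at current
  cr_mh <- mk_cradles(g, 0:1, 0:1, period = "mid_holocene")
  tm <- evaluate_trajectory(cr_mh, list(current = cur), mk_threshold(0.2))
  expect_true(all(tm$cells$survived))
  expect_error(evaluate_trajectory(cr, list(current = cur),
                                   mk_threshold(0.2)),
               "mid_holocene")
})

test_that("trajectory flags match a brute-force per-cell scan", {
  g <- small_grid(7, 7, cs = 1)
  for (i in 1:100) {
    dat <- cradlefinder:::with_seed(7000 + i, {
      n <- sample(1:12, 1)
      cells <- unique(data.frame(row = sample(0:6, n, TRUE),
                                 col = sample(0:6, n, TRUE)))
      list(cells = cells,
           mh = matrix(runif(49), 7), cur = matrix(runif(49), 7),
           thr = runif(1, 0.2, 0.8))
    })
    cr <- mk_cradles(g, dat$cells$row, dat$cells$col, "lgm")
    traj <- evaluate_trajectory(
      cr, list(mid_holocene = raster_new(g, dat$mh),
               current = raster_new(g, dat$cur)),
      mk_threshold(dat$thr))
    for (k in seq_len(nrow(traj$cells))) {
      r <- traj$cells$row[k] + 1
      cc <- traj$cells$col[k] + 1
      alive_mh <- dat$mh[r, cc] >= dat$thr
      alive_cur <- alive_mh && dat$cur[r, cc] >= dat$thr
      expect_equal(traj$cells$survived_mid_holocene[k], alive_mh)
      expect_equal(traj$cells$survived[k], alive_cur)
    }
  }
})

test_that("surviving_cradles filters by flag and nests sequentially", {
  g <- small_grid(6, 6, cs = 1)
  cr <- mk_cradles(g, rep(0:5, each = 6), rep(0:5, 6), "lgm")
  dat <- cradlefinder:::with_seed(11, list(mh = matrix(runif(36), 6),
                                           cur = matrix(runif(36), 6)))
  traj <- evaluate_trajectory(cr, list(mid_holocene = raster_new(g, dat$mh),
                                       current = raster_new(g, dat$cur)),
                              mk_threshold(0.4))
  at_cur <- surviving_cradles(traj, "current")
  at_mh <- surviving_cradles(traj, "mid_holocene")
  # filter oracle
  expect_equal(n_cradles(at_cur), sum(traj$cells$survived))
  expect_equal(n_cradles(at_mh), sum(traj$cells$survived_mid_holocene))
  # sequential nesting: survivors to current are survivors at MH
  expect_true(all(at_cur$mask$values <= at_mh$mask$values))

  # all-survive and none-survive edges
  all_t <- evaluate_trajectory(cr, list(mid_holocene = raster_new(g, 1),
                                        current = raster_new(g, 1)),
                               mk_threshold(0.5))
  expect_equal(surviving_cradles(all_t, "current")$mask$values,
               cr$mask$values)
  none_t <- evaluate_trajectory(cr, list(mid_holocene = raster_new(g, 0),
                                         current = raster_new(g, 0)),
                                mk_threshold(0.5))
  expect_equal(n_cradles(surviving_cradles(none_t, "current")), 0)
})

test_that("raising the threshold never grows the surviving set", {
  g <- small_grid(6, 6, cs = 1)
  cr <- mk_cradles(g, rep(0:5, each = 6), rep(0:5, 6), "lgm")
  maps <- cradlefinder:::with_seed(12, list(
    mid_holocene = raster_new(g, matrix(runif(36), 6)),
    current = raster_new(g, matrix(runif(36), 6))))
  prev <- NULL
  for (thr in seq(0, 1, by = 0.1)) {
    surv <- surviving_cradles(
      evaluate_trajectory(cr, maps, mk_threshold(thr)), "current")
    if (!is.null(prev)) {
      expect_true(all(surv$mask$values <= prev$mask$values))
    }
    prev <- surv
  }

  # min-mode survivors contain mid-mode contain q1-mode
  s <- new_suitability_summary("hy", values = cradlefinder:::with_seed(
    13, runif(30, 0.1, 0.9)))
  sets <- lapply(c("min", "mid", "q1"), function(m) {
    surviving_cradles(evaluate_trajectory(
      cr, maps, threshold_from_summary(s, m)), "current")$mask$values
  })
  expect_true(all(sets[[2]] <= sets[[1]]))
  expect_true(all(sets[[3]] <= sets[[2]]))
})

test_that("coverage reporting measures Chebyshev proximity to survivors", {
  g <- small_grid(6, 6, cs = 1)
  cm <- mk_cradles(g, c(1, 4), c(1, 4), "current")
  # occurrences exactly on cradle cells, radius 0 -> full coverage
  ctr <- cell_center(g, c(1, 4), c(1, 4))
  occ <- occurrence_set("hy", ctr$lon, ctr$lat)
  expect_equal(compare_with_occurrences(cm, occ, 0)$fraction_covered, 1)

  # empty expected map -> zero coverage
  empty <- cradle_map(raster_new(g, 0), "current")
  expect_equal(compare_with_occurrences(empty, occ, 0)$fraction_covered, 0)

  # distance-scan oracle on random layouts
  for (i in 1:100) {
    dat <- cradlefinder:::with_seed(8000 + i, {
      list(sr = sample(0:5, 3, TRUE), sc = sample(0:5, 3, TRUE),
           or = sample(0:5, 5, TRUE), oc = sample(0:5, 5, TRUE),
           rad = sample(0:2, 1))
    })
    cmi <- mk_cradles(g, dat$sr, dat$sc, "current")
    ctr_i <- cell_center(g, dat$or, dat$oc)
    occ_i <- occurrence_set("hy", ctr_i$lon, ctr_i$lat)
    got <- compare_with_occurrences(cmi, occ_i, dat$rad)
    cells <- unique(data.frame(row = dat$or, col = dat$oc))
    surv <- unique(data.frame(row = dat$sr, col = dat$sc))
    hit <- vapply(seq_len(nrow(cells)), function(k) {
      any(pmax(abs(surv$row - cells$row[k]),
               abs(surv$col - cells$col[k])) <= dat$rad)
    }, logical(1))
    expect_equal(got$fraction_covered, mean(hit))
    expect_equal(got$n_occurrence_cells, nrow(cells))
  }
})

test_that("a regional niche collapse removes only that region's cradles", {
  # two cradle clusters; the hybrid's suitability collapses at MH in the
  # western cluster (region X) but persists in the eastern one (region Y)
  g <- small_grid(10, 20, cs = 0.5)
  west <- expand.grid(row = 2:4, col = 2:4)
  east <- expand.grid(row = 2:4, col = 15:17)
  cr <- mk_cradles(g, c(west$row, east$row), c(west$col, east$col), "lgm")

  mh <- matrix(0.9, 10, 20)
  mh[, 1:10] <- 0.01          # collapse west of the divide
  cur <- matrix(0.9, 10, 20)
  traj <- evaluate_trajectory(cr, list(mid_holocene = raster_new(g, mh),
                                       current = raster_new(g, cur)),
                              mk_threshold(0.3))
  surv <- surviving_cradles(traj, "current")
  expect_equal(n_cradles(surv), nrow(east))
  expect_true(all(surv$cells$col >= 15))
})
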