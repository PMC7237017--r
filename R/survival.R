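#' Survival threshold from the hybrid's occupied suitability
#'
#' The lowest suitability at which the hybrid is actually observed today
#' is taken as the weakest climate it demonstrably endures; a cradle
#' whose hybrid suitability falls below it at some period is deemed
#' extinguished there. Stricter alternatives — the first quartile, or
#' the midpoint of minimum and first quartile — are exposed as modes.
#'
#' @param hybrid_current `cf_raster` of hybrid suitability under current
#'   conditions.
#' @param hybrid_occ thinned `occurrence_set` of current hybrid records.
#' @param mode `"min"` (default), `"q1"` or `"mid"`.
#' @return a `survival_threshold`: `mode`, `value`, `summary` (the
#'   underlying `suitability_summary`).
#' @export
survival_threshold <- function(hybrid_current, hybrid_occ,
                               mode = c("min", "q1", "mid")) {
  mode <- match.arg(mode)
  s <- suitability_summary(hybrid_current, hybrid_occ)
  threshold_from_summary(s, mode)
}

#' Survival threshold from an existing suitability summary
#'
#' @param summary a `suitability_summary` for the hybrid.
#' @param mode `"min"`, `"q1"` or `"mid"` ((min + q1) / 2).
#' @return a `survival_threshold`.
#' @export
threshold_from_summary <- function(summary, mode = c("min", "q1", "mid")) {
  mode <- match.arg(mode)
  stopifnot(inherits(summary, "suitability_summary"))
  value <- switch(mode, min = summary$min, q1 = summary$q1,
                  mid = (summary$min + summary$q1) / 2)
  structure(list(mode = mode, value = value, summary = summary),
            class = "survival_threshold")
}

#' @export
print.survival_threshold <- function(x, ...) {
  cat(sprintf("<survival_threshold> %s = %.5g (from %s, n = %s)\n",
              x$mode, x$value, x$summary$taxon, x$summary$n))
  invisible(x)
}

# periods evaluated after a cradle's origin, in chronological order
.periods_after <- function(origin) {
  switch(origin,
         lgm = c("mid_holocene", "current"),
         mid_holocene = "current",
         stop("cradles must originate at lgm or mid_holocene, got ", origin))
}

#' Track hybrid suitability of each cradle through time
#'
#' A cradle cell survives a period iff the hybrid's suitability there is
#' at or above the threshold. Survival is sequential: a cell that fails
#' at an earlier period stays failed at all later ones — an extinguished
#' population cannot reappear without dispersal, which the analysis
#' deliberately excludes.
#'
#' @param cradles a `cradle_map` whose `period` is the origin
#'   (`"lgm"` or `"mid_holocene"`).
#' @param hybrid_maps named list of `cf_raster` hybrid-suitability maps
#'   containing every period after the origin (`mid_holocene` and/or
#'   `current`).
#' @param threshold a `survival_threshold`.
#' @return a `cradle_trajectory`: `origin`, `threshold`, and `cells`, a
#'   data.frame with per-period suitability (`suit_<period>`), per-period
#'   survival flags (`survived_<period>`), and the final `survived` flag.
#' @export
evaluate_trajectory <- function(cradles, hybrid_maps, threshold) {
  stopifnot(inherits(cradles, "cradle_map"),
            inherits(threshold, "survival_threshold"))
  periods <- .periods_after(cradles$period)
  missing <- setdiff(periods, names(hybrid_maps))
  if (length(missing)) {
    stop("hybrid_maps is missing period(s): ", paste(missing, collapse = ", "))
  }
  cells <- cradles$cells
  alive <- rep(TRUE, nrow(cells))
  for (p in periods) {
    m <- hybrid_maps[[p]]
    stopifnot(inherits(m, "cf_raster"))
    if (!grids_compatible(m$grid, cradles$mask$grid)) {
      stop("hybrid map for ", p, " is on an incompatible grid")
    }
    s <- m$values[cbind(cells$row + 1L, cells$col + 1L)]
    ok <- !is.na(s) & s >= threshold$value
    alive <- alive & ok            # sequential: failure is permanent
    cells[[paste0("suit_", p)]] <- s
    cells[[paste0("survived_", p)]] <- alive
  }
  cells$survived <- alive
  structure(list(origin = cradles$period, threshold = threshold,
                 cells = cells, grid = cradles$mask$grid,
                 periods = periods),
            class = "cradle_trajectory")
}

#' @export
print.cradle_trajectory <- function(x, ...) {
  cat(sprintf("<cradle_trajectory> origin %s: %d cradle(s), %d surviving (%s >= %.4g)\n",
              x$origin, nrow(x$cells), sum(x$cells$survived),
              x$threshold$mode, x$threshold$value))
  invisible(x)
}

#' Cradles surviving through a period
#'
#' At `at_period = "current"` this is the expected present-day
#' distribution of the hybrid under the no-dispersal assumption.
#'
#' @param traj a `cradle_trajectory`.
#' @param at_period a period evaluated in `traj` (default the last one).
#' @return a `cradle_map` of the surviving cells.
#' @export
surviving_cradles <- function(traj, at_period = NULL) {
  stopifnot(inherits(traj, "cradle_trajectory"))
  if (is.null(at_period)) at_period <- traj$periods[length(traj$periods)]
  flag_col <- paste0("survived_", at_period)
  if (!flag_col %in% names(traj$cells)) {
    stop("period not evaluated in trajectory: ", at_period)
  }
  g <- traj$grid
  m <- matrix(0, g$n_rows, g$n_cols)
  keep <- traj$cells[traj$cells[[flag_col]], , drop = FALSE]
  if (nrow(keep)) m[cbind(keep$row + 1L, keep$col + 1L)] <- 1
  cradle_map(raster_new(g, m), period = at_period,
             provenance = list(origin = traj$origin,
                               threshold = traj$threshold))
}

#' Compare an expected distribution with observed occurrences
#'
#' Fraction of occupied cells lying within a Chebyshev (chessboard)
#' distance of `radius_cells` of a surviving cradle cell — a simple
#' coverage number for the visual map-vs-points comparison, with radius
#' 0 demanding exact cell hits.
#'
#' @param expected a `cradle_map` (e.g. from [surviving_cradles()]).
#' @param occ `occurrence_set` of observed records.
#' @param radius_cells non-negative integer neighborhood radius.
#' @return list: `fraction_covered`, `n_occurrence_cells`,
#'   `n_surviving_cells`, `radius_cells`.
#' @export
compare_with_occurrences <- function(expected, occ, radius_cells = 0) {
  stopifnot(inherits(expected, "cradle_map"), radius_cells >= 0)
  g <- expected$mask$grid
  cells <- point_to_cell(g, occ$lon, occ$lat)
  cells <- unique(cells[!is.na(cells$row), , drop = FALSE])
  surv <- expected$cells
  n_occ <- nrow(cells)
  if (n_occ == 0 || nrow(surv) == 0) {
    return(list(fraction_covered = 0, n_occurrence_cells = n_occ,
                n_surviving_cells = nrow(surv),
                radius_cells = radius_cells))
  }
  covered <- vapply(seq_len(n_occ), function(i) {
    any(pmax(abs(surv$row - cells$row[i]),
             abs(surv$col - cells$col[i])) <= radius_cells)
  }, logical(1))
  list(fraction_covered = mean(covered), n_occurrence_cells = n_occ,
       n_surviving_cells = nrow(surv), radius_cells = radius_cells)
}
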