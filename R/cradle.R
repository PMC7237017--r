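#' Summarize suitability at a taxon's current occurrences
#'
#' The distribution of model-predicted suitability at the cells where a
#' taxon is actually found defines what "low but occupied" suitability
#' means for it: the band between the minimum and the first quartile of
#' that distribution is its low-suitability range periphery. Readings
#' come from the CURRENT-conditions map at CURRENT occurrences; the
#' derived interval is then applied to any period's projection.
#'
#' @param current_suitability `cf_raster` of suitability under current
#'   conditions.
#' @param occ thinned `occurrence_set` of current presences.
#' @return an object of class `suitability_summary` with fields `taxon`,
#'   `values`, `min`, `q1` (type-7 first quartile), `n`.
#' @export
suitability_summary <- function(current_suitability, occ) {
  vals <- extract_values(current_suitability, occ)
  new_suitability_summary(occ$taxon, values = as.numeric(vals))
}

#' Construct a suitability summary directly
#'
#' Either from the raw readings, or — when only published statistics are
#' available — from the minimum and first quartile themselves.
#'
#' @param taxon taxon name.
#' @param values numeric readings in \[0, 1\] (at least 4), or `NULL`.
#' @param min,q1 the statistics, required when `values` is `NULL`.
#' @param n number of readings behind the statistics (optional when
#'   `values` is `NULL`).
#' @return a `suitability_summary`.
#' @export
new_suitability_summary <- function(taxon, values = NULL, min = NULL,
                                    q1 = NULL, n = NULL) {
  if (!is.null(values)) {
    if (length(values) < 4) {
      stop("suitability summary needs >= 4 usable readings, got ",
           length(values))
    }
    if (any(values < 0 | values > 1)) stop("suitability readings outside [0, 1]")
    min <- base::min(values)
    q1 <- unname(stats::quantile(values, 0.25, type = 7))
    n <- length(values)
  } else {
    stopifnot(!is.null(min), !is.null(q1))
    if (is.null(n)) n <- NA_integer_
  }
  if (min > q1) stop("summary has min > first quartile")
  structure(list(taxon = taxon, values = values, min = min, q1 = q1, n = n),
            class = "suitability_summary")
}

#' @export
print.suitability_summary <- function(x, ...) {
  cat(sprintf("<suitability_summary> %s: n = %s, min = %.5g, Q1 = %.5g\n",
              x$taxon, x$n, x$min, x$q1))
  invisible(x)
}

.new_interval <- function(lower, upper, rule, sources) {
  stopifnot(lower >= 0, upper <= 1)
  structure(list(lower = lower, upper = upper, rule = rule,
                 sources = sources),
            class = "lsa_interval")
}

#' @export
print.lsa_interval <- function(x, ...) {
  cat(sprintf("<lsa_interval> [%.5g, %.5g] (%s rule)\n",
              x$lower, x$upper, x$rule))
  invisible(x)
}

#' Combined low-suitability interval of two parental taxa
#'
#' The band favoring allopolyploid formation: from the HIGHER of the two
#' minima (below it one parent is absent, so interbreeding is
#' impossible) to the HIGHER of the two first quartiles (between the
#' quartiles one parent is still in its low band, supporting triploid
#' intermediates). Both ends inclusive.
#'
#' @param a,b `suitability_summary` objects for the two parents.
#' @return an `lsa_interval` with `rule = "combined"`.
#' @export
combined_interval <- function(a, b) {
  stopifnot(inherits(a, "suitability_summary"),
            inherits(b, "suitability_summary"))
  lower <- max(a$min, b$min)
  upper <- max(a$q1, b$q1)
  if (lower > upper) {
    stop(sprintf(paste0(
      "summaries admit no shared low-suitability band: higher minimum ",
      "(%.5g) exceeds higher first quartile (%.5g)"), lower, upper))
  }
  .new_interval(lower, upper, "combined", list(a = a, b = b))
}

#' Union low-suitability band of two parental taxa
#'
#' From the LOWER minimum to the higher first quartile — the widest band
#' in which at least one parent sits in its low-suitability periphery;
#' the band used to draw per-taxon low-suitability area maps.
#'
#' @param a,b `suitability_summary` objects.
#' @return an `lsa_interval` with `rule = "union"`.
#' @export
union_interval <- function(a, b) {
  stopifnot(inherits(a, "suitability_summary"),
            inherits(b, "suitability_summary"))
  .new_interval(min(a$min, b$min), max(a$q1, b$q1), "union", list(a = a, b = b))
}

#' Low-suitability-area mask
#'
#' Binary raster marking cells whose suitability lies inside the
#' interval, both bounds inclusive; nodata propagates.
#'
#' @param suitability `cf_raster` in \[0, 1\].
#' @param interval an `lsa_interval`.
#' @return binary `cf_raster`.
#' @export
lsa_mask <- function(suitability, interval) {
  stopifnot(inherits(suitability, "cf_raster"),
            inherits(interval, "lsa_interval"))
  v <- suitability$values
  raster_new(suitability$grid,
             (v >= interval$lower & v <= interval$upper) * 1)
}

#' Cellwise overlap (logical AND) of two binary masks
#'
#' @param a,b binary `cf_raster` objects on compatible grids.
#' @return binary `cf_raster`; nodata where either input is nodata.
#' @export
overlap_mask <- function(a, b) {
  stopifnot(inherits(a, "cf_raster"), inherits(b, "cf_raster"))
  if (!grids_compatible(a$grid, b$grid)) stop("overlap_mask: grid mismatch")
  raster_new(a$grid, (a$values == 1 & b$values == 1) * 1)
}

#' Filter an overlap mask by the soil mask: the cradle map
#'
#' Strict gypsophytes only grow on gypsum outcrops, so candidate cradle
#' cells outside the soil mask are discarded. The result carries the
#' period, the cell list with geographic centers, and provenance.
#'
#' @param overlap binary `cf_raster` of overlapping parental
#'   low-suitability areas.
#' @param soil binary `cf_raster` soil mask on the same grid.
#' @param period climate period label of the overlap map.
#' @param provenance optional list recorded verbatim (parent summaries,
#'   interval, soil id).
#' @return an object of class `cradle_map` with fields `mask`
#'   (binary `cf_raster`), `period`, `cells` (data.frame row, col, lon,
#'   lat), `provenance`.
#' @export
soil_filter <- function(overlap, soil, period = "current",
                        provenance = list()) {
  stopifnot(inherits(overlap, "cf_raster"), inherits(soil, "cf_raster"))
  if (!grids_compatible(overlap$grid, soil$grid)) {
    stop("soil_filter: grid mismatch")
  }
  mask <- raster_new(overlap$grid,
                     (overlap$values == 1 & soil$values == 1) * 1)
  cradle_map(mask, period = period, provenance = provenance)
}

#' Construct a cradle map from a binary mask
#'
#' @param mask binary `cf_raster`.
#' @param period climate period label.
#' @param provenance free-form provenance list.
#' @return a `cradle_map`.
#' @export
cradle_map <- function(mask, period = "current", provenance = list()) {
  idx <- which(mask$values == 1, arr.ind = TRUE)
  cells <- data.frame(row = integer(0), col = integer(0),
                      lon = numeric(0), lat = numeric(0))
  if (nrow(idx)) {
    row <- idx[, 1] - 1L; col <- idx[, 2] - 1L
    ctr <- cell_center(mask$grid, row, col)
    cells <- data.frame(row = row, col = col, lon = ctr$lon, lat = ctr$lat)
    cells <- cells[order(cells$row, cells$col), , drop = FALSE]
    rownames(cells) <- NULL
  }
  structure(list(mask = mask, period = period, cells = cells,
                 provenance = provenance),
            class = "cradle_map")
}

#' @export
print.cradle_map <- function(x, ...) {
  cat(sprintf("<cradle_map> %s: %d cradle cell(s)\n", x$period, nrow(x$cells)))
  invisible(x)
}

#' Number of cradle cells
#' @param x a `cradle_map`.
#' @return integer count.
#' @export
n_cradles <- function(x) nrow(x$cells)

#' Jaccard similarity of two binary masks
#'
#' Intersection over union of the 1-cells; used to score fitted cradles
#' against the ground-truth oracle. Defined as 1 when both are empty.
#'
#' @param a,b binary `cf_raster` objects on compatible grids.
#' @return numeric in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  stopifnot(grids_compatible(a$grid, b$grid))
  va <- a$values == 1 & !is.na(a$values)
  vb <- b$values == 1 & !is.na(b$values)
  un <- sum(va | vb)
  if (un == 0) return(1)
  sum(va & vb) / un
}
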