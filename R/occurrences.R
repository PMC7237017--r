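#' Construct an occurrence set
#'
#' Taxon-labeled point records in geographic coordinates (GBIF-style).
#' Duplicates are allowed until [thin_occurrences()] is applied.
#'
#' @param taxon taxon name (scalar character).
#' @param lon,lat numeric vectors of equal length, decimal degrees; all
#'   coordinates must be finite.
#' @return an object of class `occurrence_set`.
#' @export
occurrence_set <- function(taxon, lon, lat) {
  stopifnot(is.character(taxon), length(taxon) == 1L,
            length(lon) == length(lat))
  lon <- as.double(lon); lat <- as.double(lat)
  if (any(!is.finite(lon)) || any(!is.finite(lat))) {
    stop("occurrence coordinates must be finite")
  }
  structure(list(taxon = taxon, lon = lon, lat = lat),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %s: %d points\n", x$taxon, length(x$lon)))
  invisible(x)
}

#' Number of records in an occurrence set
#' @param occ an `occurrence_set`.
#' @return integer count.
#' @export
n_occurrences <- function(occ) length(occ$lon)

#' Read occurrences from a CSV file
#'
#' Accepts any CSV whose header contains a taxon column and coordinate
#' columns; the GBIF dialect (`decimalLongitude`/`decimalLatitude`) is
#' recognized automatically. Rows whose coordinates do not parse to
#' finite numbers are dropped and counted in the log.
#'
#' @param path CSV file path.
#' @param taxon_col,lon_col,lat_col column names; each may be a vector of
#'   acceptable names, the first one present is used.
#' @param taxon if the file has no taxon column, the name to assign.
#' @return an `occurrence_set` (of the first taxon in the file; files are
#'   expected to hold one taxon).
#' @export
read_occurrences <- function(path,
                             taxon_col = c("taxon", "species",
                                           "scientificName"),
                             lon_col = c("longitude", "decimalLongitude",
                                         "lon"),
                             lat_col = c("latitude", "decimalLatitude",
                                         "lat"),
                             taxon = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(cands, what, required = TRUE) {
    hit <- cands[cands %in% names(df)]
    if (!length(hit)) {
      if (required) stop(sprintf(
        "occurrence file %s is missing a %s column (looked for: %s)",
        path, what, paste(cands, collapse = ", ")))
      return(NULL)
    }
    hit[[1]]
  }
  lo <- pick(lon_col, "longitude")
  la <- pick(lat_col, "latitude")
  tx <- pick(taxon_col, "taxon", required = is.null(taxon))
  lon <- suppressWarnings(as.double(df[[lo]]))
  lat <- suppressWarnings(as.double(df[[la]]))
  ok <- is.finite(lon) & is.finite(lat)
  dropped <- sum(!ok)
  if (dropped > 0) {
    cf_log("read_occurrences: dropped %d row(s) with unparseable coordinates (%s)",
           dropped, path)
  }
  name <- if (!is.null(taxon)) taxon else as.character(df[[tx]][ok][1])
  out <- occurrence_set(name, lon[ok], lat[ok])
  attr(out, "n_dropped") <- dropped
  out
}

#' Write occurrences to CSV
#'
#' @param occ an `occurrence_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  stopifnot(inherits(occ, "occurrence_set"))
  utils::write.csv(
    data.frame(taxon = occ$taxon, longitude = occ$lon, latitude = occ$lat),
    path, row.names = FALSE)
  invisible(path)
}

#' Thin occurrences to one record per grid cell
#'
#' Redundant presences within one pixel at the working resolution carry
#' no extra information for a presence/background model and inflate
#' spatial autocorrelation, so each occupied cell keeps exactly one
#' record: the first in input order. Out-of-grid points are dropped and
#' logged.
#'
#' @param occ an `occurrence_set`.
#' @param grid a `grid_spec` at the predictor resolution.
#' @return a thinned `occurrence_set`; attributes `n_before`, `n_after`,
#'   `n_out_of_grid` carry the thinning report.
#' @export
thin_occurrences <- function(occ, grid) {
  stopifnot(inherits(occ, "occurrence_set"), inherits(grid, "grid_spec"))
  cells <- point_to_cell(grid, occ$lon, occ$lat)
  in_grid <- !is.na(cells$row)
  n_out <- sum(!in_grid)
  key <- cells$row[in_grid] * grid$n_cols + cells$col[in_grid]
  keep <- !duplicated(key)
  idx <- which(in_grid)[keep]
  out <- occurrence_set(occ$taxon, occ$lon[idx], occ$lat[idx])
  attr(out, "n_before") <- n_occurrences(occ)
  attr(out, "n_after") <- length(idx)
  attr(out, "n_out_of_grid") <- n_out
  cf_log("thinning %s: %d records before, %d after (one per cell)%s",
         occ$taxon, n_occurrences(occ), length(idx),
         if (n_out) sprintf(", %d out of grid", n_out) else "")
  out
}

#' Read raster values at occurrence points
#'
#' Each point reads the value of its containing cell (duplicates read
#' the cell repeatedly). Out-of-grid and nodata points are excluded and
#' counted.
#'
#' @param raster a `cf_raster`.
#' @param occ an `occurrence_set`.
#' @return numeric vector of cell values, one per usable point, with
#'   attribute `n_excluded`; errors if no point is usable.
#' @export
extract_values <- function(raster, occ) {
  stopifnot(inherits(raster, "cf_raster"), inherits(occ, "occurrence_set"))
  cells <- point_to_cell(raster$grid, occ$lon, occ$lat)
  vals <- rep(NA_real_, nrow(cells))
  ok <- !is.na(cells$row)
  vals[ok] <- raster$values[cbind(cells$row[ok] + 1L, cells$col[ok] + 1L)]
  usable <- !is.na(vals)
  if (!any(usable)) stop("extract_values: no usable points (all out of grid or nodata)")
  n_excl <- sum(!usable)
  if (n_excl > 0) {
    cf_log("extract_values: excluded %d point(s) (out of grid or nodata)", n_excl)
  }
  out <- vals[usable]
  attr(out, "n_excluded") <- n_excl
  out
}
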