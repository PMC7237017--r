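#' Define a regular geographic grid
#'
#' The grid is the single spatial frame shared by all rasters in a run:
#' square cells of `cell_size` degrees, row 0 at the northern edge,
#' column 0 at the western edge, and `origin_lon`/`origin_lat` the
#' upper-left corner of the upper-left cell. Cells are half-open,
#' `[west, east) x (south, north]`: a point on a shared edge belongs to
#' the cell to the right/below it.
#'
#' @param n_rows,n_cols positive integers, grid dimensions.
#' @param origin_lon,origin_lat upper-left corner, decimal degrees.
#' @param cell_size cell edge in degrees (square cells).
#' @param crs_id coordinate system identifier; all inputs must share it,
#'   no reprojection is performed.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, origin_lon, origin_lat, cell_size,
                      crs_id = "EPSG:4326") {
  stopifnot(n_rows > 0, n_cols > 0, cell_size > 0,
            is.finite(origin_lon), is.finite(origin_lat))
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         origin_lon = as.double(origin_lon),
         origin_lat = as.double(origin_lat),
         cell_size = as.double(cell_size), crs_id = crs_id),
    class = "grid_spec")
}

#' Test whether two grids are compatible
#'
#' Compatible means every field equal; rasters may only be combined
#' cellwise when their grids are compatible.
#'
#' @param a,b `grid_spec` objects.
#' @return logical scalar.
#' @export
grids_compatible <- function(a, b) {
  stopifnot(inherits(a, "grid_spec"), inherits(b, "grid_spec"))
  isTRUE(all.equal(unclass(a), unclass(b)))
}

#' Construct a raster on a grid
#'
#' Values are stored as an `n_rows x n_cols` matrix with `NA` marking
#' nodata cells; the nodata sentinel only appears in files on disk.
#'
#' @param grid a `grid_spec`.
#' @param values numeric matrix matching the grid dimensions, `NA` for
#'   nodata. A scalar is recycled.
#' @return an object of class `cf_raster`.
#' @export
raster_new <- function(grid, values) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(values) == 1L) {
    values <- matrix(as.double(values), grid$n_rows, grid$n_cols)
  }
  stopifnot(is.matrix(values),
            nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  storage.mode(values) <- "double"
  bad <- !is.finite(values) & !is.na(values)
  if (any(bad)) stop("raster values must be finite or NA (nodata)")
  structure(list(grid = grid, values = values), class = "cf_raster")
}

#' @export
print.cf_raster <- function(x, ...) {
  g <- x$grid
  cat(sprintf("<cf_raster> %d x %d cells, cell %.6g deg, origin (%.6g, %.6g)\n",
              g$n_rows, g$n_cols, g$cell_size, g$origin_lon, g$origin_lat))
  v <- x$values[is.finite(x$values)]
  if (length(v)) {
    cat(sprintf("  values: [%.4g, %.4g], nodata cells: %d\n",
                min(v), max(v), sum(is.na(x$values))))
  } else cat("  all nodata\n")
  invisible(x)
}

# Snap a coordinate/cell ratio that is within floating-point noise of an
# integer onto that integer, so points on shared edges land on the edge.
.snap <- function(u, eps = 1e-9) {
  r <- round(u)
  ifelse(abs(u - r) < eps, r, u)
}

#' Map points to grid cells
#'
#' Vectorized point-in-cell lookup under the half-open cell convention:
#' a point on a vertical shared edge belongs to the cell to its east, a
#' point on a horizontal shared edge to the cell to its south. Returns
#' 0-based indices; out-of-grid points get `NA` in both columns.
#'
#' @param grid a `grid_spec`.
#' @param lon,lat numeric vectors of equal length, decimal degrees.
#' @return a data.frame with integer columns `row`, `col` (0-based; `NA`
#'   marks out-of-grid points).
#' @export
point_to_cell <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "grid_spec"), length(lon) == length(lat))
  col <- floor(.snap((lon - grid$origin_lon) / grid$cell_size))
  row <- floor(.snap((grid$origin_lat - lat) / grid$cell_size))
  out <- row < 0 | row >= grid$n_rows | col < 0 | col >= grid$n_cols |
    !is.finite(row) | !is.finite(col)
  row[out] <- NA_integer_
  col[out] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Geographic centers of grid cells
#'
#' @param grid a `grid_spec`.
#' @param row,col 0-based cell indices (vectors of equal length).
#' @return a data.frame with columns `lon`, `lat` (cell centers).
#' @export
cell_center <- function(grid, row, col) {
  data.frame(
    lon = grid$origin_lon + (col + 0.5) * grid$cell_size,
    lat = grid$origin_lat - (row + 0.5) * grid$cell_size)
}

#' Read a raster from an ESRI ASCII grid file
#'
#' Plain-text single-band raster format (`ncols`/`nrows`/`xllcorner`/
#' `yllcorner`/`cellsize`/`NODATA_value` header, then rows from north to
#' south). Nodata cells come back as `NA`.
#'
#' @param path file path.
#' @param crs_id CRS identifier to attach (the format itself carries none).
#' @return a `cf_raster`.
#' @export
read_raster <- function(path, crs_id = "EPSG:4326") {
  lines <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
  hdr <- stats::setNames(as.double(kv[, 2]), tolower(kv[, 1]))
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (!k %in% names(hdr)) stop("malformed ASCII grid header: missing ", k)
  }
  nodata <- if ("nodata_value" %in% names(hdr)) hdr[["nodata_value"]] else -9999
  vals <- scan(path, what = double(), skip = 6L, quiet = TRUE)
  nr <- as.integer(hdr[["nrows"]]); nc <- as.integer(hdr[["ncols"]])
  if (length(vals) != nr * nc) stop("ASCII grid body does not match header")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  grid <- grid_spec(nr, nc,
                    origin_lon = hdr[["xllcorner"]],
                    origin_lat = hdr[["yllcorner"]] + nr * hdr[["cellsize"]],
                    cell_size = hdr[["cellsize"]], crs_id = crs_id)
  raster_new(grid, m)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' @param raster a `cf_raster`.
#' @param path output file path.
#' @param nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path, nodata = -9999) {
  stopifnot(inherits(raster, "cf_raster"))
  g <- raster$grid
  hdr <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.17g", g$origin_lon),
    sprintf("yllcorner %.17g", g$origin_lat - g$n_rows * g$cell_size),
    sprintf("cellsize %.17g", g$cell_size),
    sprintf("NODATA_value %.17g", nodata))
  m <- raster$values
  m[is.na(m)] <- nodata
  body <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
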