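#' Bundle predictor rasters into a stack
#'
#' A predictor stack is the climate input to every model fit or
#' projection: one raster per bioclimatic variable, all on one grid,
#' tagged with the climate period and the circulation model (GCM) that
#' produced it ("observed" for current conditions).
#'
#' @param layers named list of `cf_raster` objects on compatible grids.
#' @param period one of `"current"`, `"mid_holocene"`, `"lgm"`.
#' @param gcm GCM label, or `"observed"`.
#' @return an object of class `predictor_stack`.
#' @export
predictor_stack <- function(layers, period = "current", gcm = "observed") {
  stopifnot(is.list(layers), length(layers) >= 1L,
            !is.null(names(layers)), !anyDuplicated(names(layers)))
  period <- match.arg(period, c("current", "mid_holocene", "lgm"))
  g <- layers[[1]]$grid
  for (l in layers) {
    stopifnot(inherits(l, "cf_raster"))
    if (!grids_compatible(g, l$grid)) stop("stack layers on incompatible grids")
  }
  structure(list(layers = layers, period = period, gcm = gcm, grid = g),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("<predictor_stack> %s / %s: %s (%d x %d)\n", x$period, x$gcm,
              paste(names(x$layers), collapse = ", "),
              x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Variable names of a stack
#' @param stack a `predictor_stack`.
#' @return character vector.
#' @export
stack_variables <- function(stack) names(stack$layers)

#' Restrict a stack to a subset of variables
#' @param stack a `predictor_stack`.
#' @param vars variable names to keep.
#' @return a `predictor_stack`.
#' @export
stack_subset <- function(stack, vars) {
  missing <- setdiff(vars, names(stack$layers))
  if (length(missing)) {
    stop("stack is missing variable(s): ", paste(missing, collapse = ", "))
  }
  predictor_stack(stack$layers[vars], period = stack$period, gcm = stack$gcm)
}

# Matrix of predictor values for a set of cells (1-based row/col),
# columns in layer order.
.stack_values_at <- function(stack, rows1, cols1) {
  idx <- cbind(rows1, cols1)
  out <- vapply(stack$layers, function(l) l$values[idx],
                numeric(length(rows1)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L,
                                       dimnames = list(NULL, names(stack$layers)))
  out
}

# Data frame of predictors for all non-nodata cells of a stack, plus the
# 0-based cell indices; used by raster-wide prediction.
.stack_cell_frame <- function(stack) {
  g <- stack$grid
  complete <- Reduce(`&`, lapply(stack$layers, function(l) !is.na(l$values)))
  idx <- which(complete, arr.ind = TRUE)   # 1-based (row, col)
  vals <- .stack_values_at(stack, idx[, 1], idx[, 2])
  list(df = as.data.frame(vals), row = idx[, 1] - 1L, col = idx[, 2] - 1L,
       complete = complete)
}
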