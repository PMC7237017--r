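#' Assemble a presence/background training table
#'
#' Reads the predictor values at presence and background points from the
#' current-conditions stack; rows touching nodata cells are dropped and
#' counted. Presence-only data are handled as presence-versus-background
#' classification throughout.
#'
#' @param stack the `predictor_stack` to train on.
#' @param presences thinned `occurrence_set` of presences.
#' @param background `occurrence_set` of background points (see
#'   [sample_background()]).
#' @return an object of class `training_table`: `predictors`
#'   (data.frame), `label` (1 presence / 0 background), `provenance`.
#' @export
training_table <- function(stack, presences, background) {
  stopifnot(inherits(stack, "predictor_stack"))
  grab <- function(occ) {
    cells <- point_to_cell(stack$grid, occ$lon, occ$lat)
    ok <- !is.na(cells$row)
    vals <- .stack_values_at(stack, cells$row[ok] + 1L, cells$col[ok] + 1L)
    keep <- stats::complete.cases(vals)
    as.data.frame(vals[keep, , drop = FALSE])
  }
  p <- grab(presences); b <- grab(background)
  if (nrow(p) < 1 || nrow(b) < 1) {
    stop("training table needs at least one presence and one background row")
  }
  dropped <- (n_occurrences(presences) - nrow(p)) +
    (n_occurrences(background) - nrow(b))
  if (dropped > 0) cf_log("training_table: dropped %d nodata row(s)", dropped)
  structure(list(predictors = rbind(p, b),
                 label = c(rep(1, nrow(p)), rep(0, nrow(b))),
                 provenance = list(taxon = presences$taxon,
                                   period = stack$period, gcm = stack$gcm)),
            class = "training_table")
}

#' Sample background points uniformly over the landscape
#'
#' Draws `n` distinct non-nodata cells uniformly at random, excluding
#' cells holding a presence, and returns their centers. The default
#' scheme elsewhere in the pipeline is 10 background points per
#' presence with a floor of 1000.
#'
#' @param stack a `predictor_stack` (defines the eligible cells).
#' @param n number of background points.
#' @param seed integer seed.
#' @param exclude `occurrence_set` whose cells are excluded (typically
#'   the presences), or `NULL`.
#' @return an `occurrence_set` named `"background"`.
#' @export
sample_background <- function(stack, n, seed, exclude = NULL) {
  stopifnot(inherits(stack, "predictor_stack"), n >= 1)
  g <- stack$grid
  complete <- Reduce(`&`, lapply(stack$layers, function(l) !is.na(l$values)))
  eligible <- which(complete)
  if (!is.null(exclude)) {
    cells <- point_to_cell(g, exclude$lon, exclude$lat)
    ok <- !is.na(cells$row)
    # matrix linear index is column-major: row + col * n_rows (1-based row)
    used <- (cells$row[ok] + 1L) + cells$col[ok] * g$n_rows
    eligible <- setdiff(eligible, used)
  }
  if (length(eligible) < n) {
    stop(sprintf("only %d eligible background cell(s), need %d",
                 length(eligible), n))
  }
  picked <- with_seed(seed, sample(eligible, n, replace = FALSE))
  row <- (picked - 1L) %% g$n_rows
  col <- (picked - 1L) %/% g$n_rows
  ctr <- cell_center(g, row, col)
  occurrence_set("background", ctr$lon, ctr$lat)
}

#' Registered model algorithms
#' @return character vector of algorithm names.
#' @export
sdm_algorithms <- function() c("glm", "rf", "mars", "maxent")

# ---- single-model fits ----------------------------------------------------
# Each algorithm maps a predictor data.frame + 0/1 label to an opaque
# fit whose predictions are suitabilities in [0, 1].

# maxent surrogate feature expansion: linear + quadratic + pairwise
# products, the log-linear feature classes of the original method.
.maxent_features <- function(df) {
  X <- as.matrix(df)
  feats <- cbind(X, X^2)
  colnames(feats) <- c(colnames(X), paste0(colnames(X), "_sq"))
  nv <- ncol(X)
  if (nv >= 2) {
    for (i in seq_len(nv - 1)) {
      for (j in seq(i + 1, nv)) {
        feats <- cbind(feats, X[, i] * X[, j])
        colnames(feats)[ncol(feats)] <-
          paste0(colnames(X)[i], "_x_", colnames(X)[j])
      }
    }
  }
  feats
}

fit_model <- function(algorithm, predictors, label, seed) {
  algorithm <- match.arg(algorithm, sdm_algorithms())
  vars <- colnames(predictors)
  fit <- switch(algorithm,
    glm = {
      # logistic regression with linear + quadratic response per variable
      rhs <- paste(vapply(vars, function(v) {
        sprintf("%s + I(%s^2)", v, v)
      }, ""), collapse = " + ")
      df <- cbind(predictors, .cf_label = label)
      suppressWarnings(stats::glm(
        stats::as.formula(paste(".cf_label ~", rhs)),
        family = stats::binomial(), data = df))
    },
    rf = {
      df <- cbind(predictors, .cf_label = factor(label, levels = c(0, 1)))
      # probability forest with large terminal nodes: class-frequency
      # leaves memorize training presences otherwise, inflating the
      # suitability read back at occupied cells
      ranger::ranger(
        dependent.variable.name = ".cf_label", data = df,
        num.trees = 300, probability = TRUE, seed = as.integer(seed),
        num.threads = 1L, min.node.size = max(20, round(nrow(df) * 0.02)),
        respect.unordered.factors = TRUE)
    },
    mars = with_seed(seed, fit_mars(predictors, label)),
    maxent = {
      feats <- .maxent_features(predictors)
      keep <- apply(feats, 2, stats::sd) > 0
      if (sum(keep) < 2) {
        # degenerate table: constant features; intercept-only model
        structure(list(intercept_only = TRUE, p = mean(label)),
                  class = "cf_maxent")
      } else {
        cv <- with_seed(seed, glmnet::cv.glmnet(
          feats[, keep, drop = FALSE], label, family = "binomial",
          alpha = 1, nfolds = 5, standardize = TRUE))
        structure(list(intercept_only = FALSE, cv = cv, keep = keep),
                  class = "cf_maxent")
      }
    })
  structure(list(algorithm = algorithm, fit = fit, vars = vars),
            class = "cf_sdm_fit")
}

predict_sdm <- function(object, newdata) {
  stopifnot(inherits(object, "cf_sdm_fit"))
  newdata <- newdata[, object$vars, drop = FALSE]
  p <- switch(object$algorithm,
    glm = as.vector(stats::predict(object$fit, newdata = newdata,
                                   type = "response")),
    rf = {
      pr <- stats::predict(object$fit, data = newdata,
                           num.threads = 1L)$predictions
      pr[, "1"]
    },
    mars = predict_mars(object$fit, newdata),
    maxent = {
      f <- object$fit
      if (f$intercept_only) {
        rep(f$p, nrow(newdata))
      } else {
        feats <- .maxent_features(newdata)[, f$keep, drop = FALSE]
        as.vector(stats::predict(f$cv, newx = feats, s = "lambda.min",
                                 type = "response"))
      }
    })
  pmin(pmax(p, 0), 1)
}

#' Fit one bootstrap replicate of an algorithm
#'
#' Resamples the table rows with replacement (in-bag) for training and
#' keeps the out-of-bag rows for evaluation. A resample that lands all
#' on one label is retried with the next seed (logged), up to 10 times.
#'
#' @param algorithm one of [sdm_algorithms()].
#' @param table a `training_table`.
#' @param replicate_seed integer seed for the resample and the fit.
#' @return a `model_replicate`: `algorithm`, `seed`, `fit`, `inbag`,
#'   `oob`, and `metrics` (filled by [evaluate()], `NULL` until then).
#' @export
fit_replicate <- function(algorithm, table, replicate_seed) {
  stopifnot(inherits(table, "training_table"))
  n <- length(table$label)
  seed <- as.integer(replicate_seed)
  inbag <- NULL
  for (try in 0:10) {
    cand <- with_seed(seed + try, sample.int(n, n, replace = TRUE))
    if (length(unique(table$label[cand])) == 2L) {
      inbag <- cand
      if (try > 0) cf_log("fit_replicate: degenerate resample, retried %d time(s)", try)
      break
    }
  }
  if (is.null(inbag)) {
    stop("fit_replicate: could not draw a resample containing both labels")
  }
  fit <- fit_model(algorithm, table$predictors[inbag, , drop = FALSE],
                   table$label[inbag], seed)
  rep <- structure(
    list(algorithm = algorithm, seed = seed, fit = fit, inbag = inbag,
         oob = setdiff(seq_len(n), inbag), metrics = NULL),
    class = "model_replicate")
  rep$metrics <- evaluate(rep, table)
  rep
}

#' Predict suitability from one replicate
#'
#' @param model a `model_replicate`.
#' @param newdata data.frame of predictor values.
#' @return suitabilities in \[0, 1\].
#' @export
predict_replicate <- function(model, newdata) {
  predict_sdm(model$fit, newdata)
}

#' Fit a full bootstrap ensemble for one taxon
#'
#' Thirty bootstrap replicates (by default) of each of the four
#' algorithm families, each scored out-of-bag with AUC and TSS. Member
#' weights for the weighted-average ensemble default to TSS floored at
#' zero (AUC available as an alternative).
#'
#' @param table a `training_table`.
#' @param algorithms subset of [sdm_algorithms()].
#' @param n_replicates bootstrap replicates per algorithm (default 30).
#' @param seed base seed; each replicate derives its own.
#' @param weight_metric `"tss"` (default) or `"auc"`.
#' @return an `sdm_ensemble`: `members` (list of `model_replicate`),
#'   `weights`, `variables`, `taxon`, `evaluation` (data.frame of
#'   per-member metrics).
#' @export
fit_ensemble <- function(table, algorithms = sdm_algorithms(),
                         n_replicates = 30, seed = 1,
                         weight_metric = c("tss", "auc")) {
  weight_metric <- match.arg(weight_metric)
  members <- list()
  for (alg in algorithms) {
    for (i in seq_len(n_replicates)) {
      members[[length(members) + 1L]] <-
        fit_replicate(alg, table, derive_seed(seed, paste(alg, i)))
    }
  }
  ev <- data.frame(
    algorithm = vapply(members, function(m) m$algorithm, ""),
    replicate = unlist(lapply(algorithms, function(a) seq_len(n_replicates))),
    auc = vapply(members, function(m) m$metrics$auc, 0),
    tss = vapply(members, function(m) m$metrics$tss, 0),
    tss_threshold = vapply(members, function(m) m$metrics$tss_threshold, 0))
  w <- if (weight_metric == "tss") pmax(ev$tss, 0) else ev$auc
  if (all(w == 0)) w <- rep(1, length(w))
  structure(list(members = members, weights = w,
                 variables = colnames(table$predictors),
                 taxon = table$provenance$taxon, evaluation = ev),
            class = "sdm_ensemble")
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf("<sdm_ensemble> %s: %d members (%s)\n", x$taxon,
              length(x$members),
              paste(unique(x$evaluation$algorithm), collapse = ", ")))
  invisible(x)
}

#' Out-of-bag AUC of the whole ensemble
#'
#' Each training row is scored by the weighted mean of the member
#' predictions for which that row was out-of-bag, and a single AUC is
#' computed from those aggregated scores — the standard out-of-bag
#' construction for bagged ensembles (rows never see a model they
#' helped train).
#'
#' @param ensemble an `sdm_ensemble`.
#' @param table the `training_table` it was fitted on.
#' @return AUC in \[0, 1\].
#' @export
ensemble_oob_auc <- function(ensemble, table) {
  stopifnot(inherits(ensemble, "sdm_ensemble"),
            inherits(table, "training_table"))
  n <- length(table$label)
  num <- den <- rep(0, n)
  for (k in seq_along(ensemble$members)) {
    m <- ensemble$members[[k]]
    w <- ensemble$weights[k]
    if (w <= 0 || length(m$oob) == 0L) next
    p <- predict_replicate(m, table$predictors[m$oob, , drop = FALSE])
    num[m$oob] <- num[m$oob] + w * p
    den[m$oob] <- den[m$oob] + w
  }
  ok <- den > 0
  sc <- num[ok] / den[ok]
  lab <- table$label[ok]
  if (length(unique(lab)) < 2L) stop("out-of-bag scores lack a label")
  auc_score(sc[lab == 1], sc[lab == 0])
}

#' Mean out-of-bag metrics of an ensemble, by algorithm
#'
#' @param ensemble an `sdm_ensemble`.
#' @return data.frame with one row per algorithm: mean AUC and TSS.
#' @export
ensemble_evaluation <- function(ensemble) {
  ev <- ensemble$evaluation
  out <- do.call(rbind, lapply(split(ev, ev$algorithm), function(d) {
    data.frame(algorithm = d$algorithm[1], auc = mean(d$auc),
               tss = mean(d$tss))
  }))
  rownames(out) <- NULL
  out[order(out$algorithm), , drop = FALSE]
}

#' Weighted cellwise mean and spread of member maps
#'
#' The ensemble map is the weighted mean of the member suitability
#' rasters; uncertainty is the weighted standard deviation. Nodata
#' propagates from any member.
#'
#' @param members list of `cf_raster` objects on one grid.
#' @param weights non-negative weights, not all zero.
#' @param period,gcm tags for the result.
#' @return an `ensemble_prediction`: `mean` and `sd` rasters, `weights`,
#'   `period`, `gcm`.
#' @export
weighted_ensemble <- function(members, weights = rep(1, length(members)),
                              period = "current", gcm = "observed") {
  stopifnot(length(members) >= 1, length(weights) == length(members),
            all(weights >= 0), any(weights > 0))
  g <- members[[1]]$grid
  for (m in members) {
    if (!grids_compatible(g, m$grid)) stop("weighted_ensemble: grid mismatch")
  }
  W <- sum(weights)
  mean_m <- Reduce(`+`, Map(function(m, w) m$values * w, members,
                            as.list(weights))) / W
  var_m <- Reduce(`+`, Map(function(m, w) w * (m$values - mean_m)^2,
                           members, as.list(weights))) / W
  # where members agree exactly the spread is exactly zero (and the mean
  # is the common value), untouched by floating-point accumulation
  lo <- Reduce(pmin, lapply(members, function(m) m$values))
  hi <- Reduce(pmax, lapply(members, function(m) m$values))
  agree <- !is.na(lo) & !is.na(hi) & lo == hi
  var_m[agree] <- 0
  mean_m[agree] <- lo[agree]
  structure(list(mean = raster_new(g, mean_m),
                 sd = raster_new(g, sqrt(pmax(var_m, 0))),
                 weights = weights, period = period, gcm = gcm),
            class = "ensemble_prediction")
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  cat(sprintf("<ensemble_prediction> %s / %s\n", x$period, x$gcm))
  print(x$mean)
  invisible(x)
}

#' Project an ensemble onto a predictor stack
#'
#' Every member predicts on the stack's cells and the weighted average
#' is formed; the output carries the stack's period and GCM tags.
#' Projecting onto the training stack reproduces the training-period
#' ensemble.
#'
#' @param ensemble an `sdm_ensemble`.
#' @param stack a `predictor_stack` holding every training variable.
#' @return an `ensemble_prediction`.
#' @export
project <- function(ensemble, stack) {
  stopifnot(inherits(ensemble, "sdm_ensemble"),
            inherits(stack, "predictor_stack"))
  missing <- setdiff(ensemble$variables, names(stack$layers))
  if (length(missing)) {
    stop("projection stack is missing variable(s): ",
         paste(missing, collapse = ", "))
  }
  cf <- .stack_cell_frame(stack_subset(stack, ensemble$variables))
  g <- stack$grid
  member_rasters <- lapply(ensemble$members, function(m) {
    v <- matrix(NA_real_, g$n_rows, g$n_cols)
    v[cbind(cf$row + 1L, cf$col + 1L)] <- predict_replicate(m, cf$df)
    raster_new(g, v)
  })
  weighted_ensemble(member_rasters, ensemble$weights,
                    period = stack$period, gcm = stack$gcm)
}

#' Consensus across GCM-specific predictions
#'
#' For a past period each pseudo-GCM yields its own projection; the
#' consensus map is their unweighted cellwise mean, and the cellwise
#' standard deviation across GCMs is kept as the uncertainty layer.
#'
#' @param per_gcm list of `ensemble_prediction` objects for one period.
#' @return an `ensemble_prediction` with `gcm = "consensus"`.
#' @export
gcm_consensus <- function(per_gcm) {
  stopifnot(length(per_gcm) >= 1)
  period <- unique(vapply(per_gcm, function(p) p$period, ""))
  if (length(period) != 1L) {
    stop("gcm_consensus: predictions mix periods: ",
         paste(period, collapse = ", "))
  }
  out <- weighted_ensemble(lapply(per_gcm, function(p) p$mean),
                           period = period, gcm = "consensus")
  out
}
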