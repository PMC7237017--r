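#' Correlation structure of a predictor stack
#'
#' Pearson correlations between layers over a seeded random sample of
#' complete cells, single-linkage clustering on the distance `1 - |r|`,
#' and groups cut at a distance threshold (default 0.3, i.e. variables
#' with |r| >= 0.7 share a group — the common collinearity rule of
#' thumb). Collinear predictors inflate model variance and blur
#' variable-contribution estimates, so one representative per group is
#' kept downstream.
#'
#' @param stack a `predictor_stack` with at least two layers.
#' @param sample_cells number of cells to sample (>= 30); all complete
#'   cells are used when fewer exist.
#' @param seed integer seed for the cell sample.
#' @param threshold distance (`1 - |r|`) at which groups are cut.
#' @return a `correlation_report`: `variables`, `r` (correlation
#'   matrix), `linkage` (hclust object), `groups` (named integer
#'   vector), `threshold`.
#' @export
correlation_report <- function(stack, sample_cells = 2000, seed = 1,
                               threshold = 0.3) {
  stopifnot(inherits(stack, "predictor_stack"),
            length(stack$layers) >= 2, sample_cells >= 30)
  cf <- .stack_cell_frame(stack)
  n <- nrow(cf$df)
  idx <- if (n > sample_cells) {
    with_seed(seed, sample.int(n, sample_cells))
  } else seq_len(n)
  X <- as.matrix(cf$df[idx, , drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  r <- suppressWarnings(stats::cor(X))
  if (any(sds == 0)) {
    warning("zero-variance layer(s) in correlation sample: ",
            paste(colnames(X)[sds == 0], collapse = ", "),
            "; affected correlations reported as 0")
    r[is.na(r)] <- 0
    diag(r) <- 1
  }
  h <- stats::hclust(stats::as.dist(1 - abs(r)), method = "single")
  groups <- stats::cutree(h, h = threshold)
  structure(list(variables = colnames(X), r = r, linkage = h,
                 groups = groups, threshold = threshold),
            class = "correlation_report")
}

#' Jackknife test of variable contribution
#'
#' For every predictor, fit the model on that variable alone and on all
#' variables except it, scoring both fits on the training data with the
#' chosen metric (AUC by default). A variable whose "alone" score is
#' high carries signal by itself; one whose removal barely moves the
#' "without" score is redundant.
#'
#' @param occ thinned presence `occurrence_set`.
#' @param background background `occurrence_set`.
#' @param stack the `predictor_stack` of candidate variables.
#' @param algorithm one of [sdm_algorithms()] (default `"glm"`).
#' @param seed integer seed for the fits.
#' @return a `jackknife_report` data.frame: `variable`, `alone_score`,
#'   `without_score` (`NA` for a single-variable stack), with attribute
#'   `metric`.
#' @export
jackknife_contribution <- function(occ, background, stack,
                                   algorithm = "glm", seed = 1) {
  stopifnot(n_occurrences(occ) >= 1, n_occurrences(background) >= 1)
  algorithm <- match.arg(algorithm, sdm_algorithms())
  table <- training_table(stack, occ, background)
  vars <- colnames(table$predictors)
  score_on <- function(cols) {
    fit <- fit_model(algorithm, table$predictors[, cols, drop = FALSE],
                     table$label, derive_seed(seed, paste(cols, collapse = "+")))
    sc <- predict_sdm(fit, table$predictors[, cols, drop = FALSE])
    auc_score(sc[table$label == 1], sc[table$label == 0])
  }
  alone <- vapply(vars, function(v) score_on(v), 0)
  without <- if (length(vars) >= 2) {
    vapply(vars, function(v) score_on(setdiff(vars, v)), 0)
  } else rep(NA_real_, length(vars))
  out <- data.frame(variable = vars, alone_score = unname(alone),
                    without_score = unname(without))
  attr(out, "metric") <- "auc"
  class(out) <- c("jackknife_report", class(out))
  out
}

#' Select variables from correlation groups and jackknife scores
#'
#' Within every correlation group the variable with the highest "alone"
#' jackknife score is kept (ties broken by variable name); forced
#' variables — e.g. a dry-season precipitation variable retained for
#' ecological reasons regardless of its score — are added afterwards.
#'
#' @param corr a `correlation_report`.
#' @param jack a `jackknife_report` covering the same variables.
#' @param forced variable names always kept.
#' @return character vector of selected names, in stack order.
#' @export
select_variables <- function(corr, jack, forced = character()) {
  stopifnot(inherits(corr, "correlation_report"))
  if (!all(forced %in% corr$variables)) {
    stop("forced variable(s) not in the candidate set: ",
         paste(setdiff(forced, corr$variables), collapse = ", "))
  }
  scores <- stats::setNames(jack$alone_score, jack$variable)
  kept <- vapply(split(names(corr$groups), corr$groups), function(vs) {
    s <- scores[vs]
    best <- vs[s == max(s)]
    sort(best)[1]          # deterministic tie-break by name
  }, "")
  out <- union(kept, forced)
  out[order(match(out, corr$variables))]
}
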