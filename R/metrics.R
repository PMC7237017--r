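#' Area under the ROC curve by pairwise concordance
#'
#' Probability that a randomly chosen presence score exceeds a randomly
#' chosen background score, with ties counted one half — computed via
#' midranks (exactly the Mann-Whitney statistic, identical to full
#' pairwise enumeration).
#'
#' @param pos scores at presences.
#' @param neg scores at background points.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(pos, neg) {
  stopifnot(length(pos) >= 1, length(neg) >= 1)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' True Skill Statistic maximized over thresholds
#'
#' TSS = sensitivity + specificity - 1 at the best threshold, where a
#' point is predicted present when its score is >= the threshold and
#' candidate thresholds are the sorted unique observed scores.
#'
#' @param pos scores at presences.
#' @param neg scores at background points.
#' @return list with `tss` (in \[-1, 1\]) and `threshold` (the maximizing
#'   threshold).
#' @export
tss_score <- function(pos, neg) {
  stopifnot(length(pos) >= 1, length(neg) >= 1)
  thr <- sort(unique(c(pos, neg)))
  # vapply over thresholds; score sets are small (bootstrap OOB)
  tss <- vapply(thr, function(t) {
    mean(pos >= t) + mean(neg < t) - 1
  }, 0)
  best <- which.max(tss)
  list(tss = tss[best], threshold = thr[best])
}

#' Evaluate a fitted replicate with AUC and TSS
#'
#' Scores the replicate on its out-of-bag rows; when the out-of-bag set
#' lacks one of the labels the full table is used instead (logged).
#'
#' @param model a `model_replicate` from [fit_replicate()].
#' @param table the `training_table` the replicate was fitted on.
#' @return an `eval_metrics` list: `auc`, `tss`, `tss_threshold`,
#'   `eval_on` (`"oob"` or `"full"`).
#' @export
evaluate <- function(model, table) {
  stopifnot(inherits(model, "model_replicate"),
            inherits(table, "training_table"))
  idx <- model$oob
  lab <- table$label[idx]
  eval_on <- "oob"
  if (length(unique(lab)) < 2L || length(idx) == 0L) {
    cf_log("evaluate: out-of-bag set lacks a label, scoring on full table")
    idx <- seq_along(table$label)
    lab <- table$label
    eval_on <- "full"
  }
  sc <- predict_replicate(model, table$predictors[idx, , drop = FALSE])
  t <- tss_score(sc[lab == 1], sc[lab == 0])
  structure(list(auc = auc_score(sc[lab == 1], sc[lab == 0]),
                 tss = t$tss, tss_threshold = t$threshold,
                 eval_on = eval_on),
            class = "eval_metrics")
}
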