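# MARS-style hinge regression: forward selection of mirrored hinge-basis
# pairs by residual sum of squares, then backward pruning by generalized
# cross-validation (GCV). Least-squares on the 0/1 label, predictions
# clipped to [0, 1] — the classic formulation applied to
# presence/background data.

.hinge_basis <- function(X, terms) {
  n <- nrow(X)
  B <- matrix(1, n, 1L)
  for (tm in terms) {
    h <- X[, tm$var] - tm$knot
    B <- cbind(B, if (tm$dir > 0) pmax(h, 0) else pmax(-h, 0))
  }
  B
}

.gcv <- function(rss, n, n_terms, penalty = 3) {
  # effective parameters: columns plus a penalty per knot
  ep <- n_terms + penalty * (n_terms - 1) / 2
  if (ep >= n) return(Inf)
  (rss / n) / (1 - ep / n)^2
}

fit_mars <- function(X, y, max_terms = 15L, n_knots = 7L, penalty = 3) {
  X <- as.matrix(X)
  n <- nrow(X)
  terms <- list()
  B <- matrix(1, n, 1L)
  fit <- stats::lm.fit(B, y)
  rss <- sum(fit$residuals^2)
  # candidate knots: interior quantiles per variable
  knots <- lapply(seq_len(ncol(X)), function(j) {
    unique(stats::quantile(X[, j], probs = seq_len(n_knots) / (n_knots + 1),
                           type = 7, names = FALSE))
  })
  while (ncol(B) + 2L <= max_terms) {
    best <- NULL
    for (j in seq_len(ncol(X))) {
      for (k in knots[[j]]) {
        h <- X[, j] - k
        cand <- cbind(B, pmax(h, 0), pmax(-h, 0))
        f <- stats::lm.fit(cand, y)
        r <- sum(f$residuals^2)
        if (is.null(best) || r < best$rss - 1e-12) {
          best <- list(rss = r, var = j, knot = k)
        }
      }
    }
    if (is.null(best) || best$rss >= rss * (1 - 1e-4)) break
    terms <- c(terms,
               list(list(var = best$var, knot = best$knot, dir = 1),
                    list(var = best$var, knot = best$knot, dir = -1)))
    h <- X[, best$var] - best$knot
    B <- cbind(B, pmax(h, 0), pmax(-h, 0))
    rss <- best$rss
  }
  # backward pruning by GCV over nested deletions
  keep <- seq_along(terms)
  best_keep <- keep
  best_gcv <- .gcv(rss, n, length(keep) + 1L, penalty)
  cur <- keep
  while (length(cur) > 0L) {
    gcvs <- vapply(seq_along(cur), function(i) {
      sub <- cur[-i]
      Bs <- .hinge_basis(X, terms[sub])
      .gcv(sum(stats::lm.fit(Bs, y)$residuals^2), n, length(sub) + 1L, penalty)
    }, 0)
    i <- which.min(gcvs)
    cur <- cur[-i]
    if (gcvs[i] < best_gcv) {
      best_gcv <- gcvs[i]
      best_keep <- cur
    }
  }
  terms <- terms[best_keep]
  B <- .hinge_basis(X, terms)
  coef <- stats::lm.fit(B, y)$coefficients
  coef[is.na(coef)] <- 0
  structure(list(terms = terms, coef = coef, vars = colnames(X)),
            class = "cf_mars")
}

predict_mars <- function(object, X) {
  X <- as.matrix(X)
  B <- .hinge_basis(X, object$terms)
  pmin(pmax(as.vector(B %*% object$coef), 0), 1)
}
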