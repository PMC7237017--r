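#' Derive a reproducible sub-seed from a base seed and a label
#'
#' Every stochastic step in the pipeline draws its own seed from a single
#' base seed plus a step label, so that stages can be rerun independently
#' without sharing RNG state. The derivation is a small string hash kept
#' below 2^31 so it is a valid R integer seed.
#'
#' @param base integer base seed.
#' @param label character label naming the stochastic step.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(base, label) {
  stopifnot(is.numeric(base), length(base) == 1L, is.character(label))
  h <- as.double(base %% 2147483647)
  for (code in utf8ToInt(paste(label, collapse = "/"))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Internal logging: messages are informative, never warnings, so that
# pipelines can run quietly with suppressMessages().
cf_log <- function(...) message("[cradlefinder] ", sprintf(...))
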