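#' @useDynLib occuCAR, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom rpois rnbinom sd cor quantile plogis qlogis
#' @importFrom utils write.csv read.csv head
NULL

invlogit <- stats::plogis
logit <- stats::qlogis

# Evaluate `expr` under a fixed RNG state and restore the caller's state
# afterwards, so generators are pure functions of (parameters, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministic seed derivation used by the pipeline driver: each stage
#' gets its own stream so that adding a stage never perturbs another
#' stage's randomness. Result is always in `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  s <- (as.double(master) * 7919 + h * 104729) %% (2^31 - 2)
  as.integer(s) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}
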