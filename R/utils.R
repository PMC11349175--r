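# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a child seed from a master seed
#'
#' Deterministic integer hash used to give every stochastic stage (and every
#' bootstrap replicate, imputation, and simulated patient) its own
#' reproducible stream, independent of execution order. Stays below 2^31.
#'
#' @param seed master integer seed
#' @param ... further integer components identifying the sub-stream
#' @return a single integer seed
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  for (p in parts) {
    h <- (h * 69069 + as.double(p) %% 2147483647 + 1) %% 2147483647
  }
  as.integer(h)
}

# Run expr under a local RNG state seeded by `seed`, restoring the caller's
# RNG afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

# logit helpers
plogis_ <- stats::plogis
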