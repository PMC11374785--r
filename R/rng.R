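# Seed plumbing. Operations that accept `seed` must behave as pure functions
# of their inputs and must not disturb the caller's RNG stream.

#' Evaluate an expression under a local RNG seed
#'
#' When `seed` is `NULL` the expression simply uses (and advances) the global
#' RNG stream. Otherwise the global `.Random.seed` is saved, the seed is set,
#' the expression is evaluated, and the previous RNG state is restored.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministic stream splitting: child seeds stay strictly below 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (((as.numeric(seed) %% 1000003) + 1) * 2039 + 101 * as.numeric(k) + 17) %% 2147483629
}
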