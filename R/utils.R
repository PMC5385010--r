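#' Evaluate an expression with a locally seeded RNG
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so seeded operations do not disturb the global
#' random stream. With `seed = NULL` the expression runs on the current
#' stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialize a RNG state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' One-tailed permutation p-value
#'
#' @param exceed number of permuted statistics at least as extreme as observed.
#' @param n_perm number of permutations.
#' @return `(exceed + 1) / (n_perm + 1)`.
#' @keywords internal
perm_pvalue <- function(exceed, n_perm) (exceed + 1) / (n_perm + 1)

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

#' Check that a vector holds non-negative whole numbers
#' @keywords internal
is_count_vector <- function(x) {
  is.numeric(x) && !anyNA(x) && all(x >= 0) && all(abs(x - round(x)) < 1e-8)
}
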