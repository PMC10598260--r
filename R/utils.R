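#' Run an expression under a local, seeded RNG state
#'
#' Evaluates `expr` with the RNG seeded to `seed`, then restores the
#' caller's RNG state so seeded helpers do not disturb an enclosing
#' simulation stream. A `NULL` seed leaves the stream untouched.
#'
#' @param seed integer scalar or `NULL`
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# softmax over rows of a matrix of linear predictors; -Inf entries map to 0
softmax_rows <- function(eta) {
  m <- apply(eta, 1L, max)
  w <- exp(eta - m)
  w / rowSums(w)
}

# derive integer child seeds from one parent seed, all < 2^31
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}
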