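#' Evaluate an expression under a local, reproducible RNG state
#'
#' All stochastic operations in the package funnel their randomness through
#' this helper: the global RNG state is saved, the given seed installed
#' (Mersenne-Twister, Inversion), the expression evaluated, and the previous
#' state restored.  Identical seeds therefore give identical draws regardless
#' of the surrounding session.
#'
#' @param seed integer seed (kept below 2^31 by callers).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# derive a stream of child seeds from one master seed, all < 2^31
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

stop_if_not_finite <- function(x, name) {
  if (!all(is.finite(x))) stop(sprintf("`%s` must be finite", name), call. = FALSE)
  invisible(x)
}
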