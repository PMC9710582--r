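# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards. When seed is NULL the expression runs on the
# ambient stream.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

relu <- function(x) pmax(x, 0)

# numerically safe log(1 + exp(x))
softplus <- function(x) {
  out <- x
  small <- x < 30
  out[small] <- log1p(exp(x[small]))
  out
}

sigmoid <- function(x) stats::plogis(x)

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop("non-finite values in ", what)
  invisible(x)
}
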