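## Internal helpers shared across modules.

## Evaluate `expr` under a fixed RNG state without disturbing the caller's
## stream. All stochastic operations in the package funnel through this so
## results are pure functions of their `seed` argument.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

## min-max scale a vector to [0, 1]; constant input maps to 0.
minmax01 <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
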