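# Internal helpers shared across modules.

# Evaluate expr with a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Population standard deviation (divide by n, not n - 1).
sd_pop <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}
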