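clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run `expr` with a seeded RNG, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot_scalar_num(seed, "seed")
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
  }
  force(expr)
}

# Population standard deviation (divide by n), used for pixel ROIs where the
# quantity of interest is the noise of a fixed region.
sd_pop <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}
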