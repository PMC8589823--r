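#' @import methods
#' @importFrom stats dnbinom pnbinom qnbinom rnbinom rnorm runif sd median
#' @importFrom utils head tail write.csv read.csv modifyList
NULL

## Numerically stable log(sum(exp(x))); returns -Inf for empty / all -Inf input.
logSumExp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
## caller's state afterwards. All stochastic operations in the package funnel
## through this so that results are reproducible and order-independent.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

## Derive a child seed from a master seed and a counter; stays below 2^31.
childSeed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 16807) %%
               2147483647)
}

isProbVector <- function(p, tol = 1e-12) {
  is.numeric(p) && length(p) >= 1L && all(is.finite(p)) && all(p >= 0) &&
    abs(sum(p) - 1) <= tol
}

stopIfNotProb <- function(p, what, tol = 1e-12) {
  if (!isProbVector(p, tol))
    stop(sprintf("%s must be a probability vector summing to 1 (got sum %.15g)",
                 what, sum(p)), call. = FALSE)
  invisible(TRUE)
}
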