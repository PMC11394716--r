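#' @import methods
#' @importFrom stats coef cor lm predict rnorm runif sd var setNames quantile median
#' @importFrom utils write.csv packageVersion head tail
NULL

## Evaluate expr with a fixed RNG seed, restoring the caller's RNG state after.
## All package randomness flows through this so a top-level seed is reproducible.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop("'seed' must be coercible to a finite integer")
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

## Derive a stream of sub-seeds from one master seed, kept within 32-bit range.
deriveSeed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + 1013L * as.integer(offset)) %% 2147483629L
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

assertCount <- function(x, name, min = 1L) {
  stopIfNot(length(x) == 1L && is.finite(x) && x == round(x) && x >= min,
            sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

assertScalar <- function(x, name, min = -Inf) {
  stopIfNot(length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min,
            sprintf("'%s' must be a single finite number%s", name,
                    if (is.finite(min)) sprintf(" >= %g", min) else ""))
  as.numeric(x)
}

assertSymmetric <- function(M, name = "matrix", tol = 1e-8) {
  stopIfNot(is.matrix(M) && nrow(M) == ncol(M),
            sprintf("'%s' must be a square matrix", name))
  dev <- max(abs(M - t(M)))
  scale <- max(abs(M), 1)
  stopIfNot(dev <= tol * scale,
            sprintf("'%s' is not symmetric (max asymmetry %.3g)", name, dev))
  (M + t(M)) / 2
}
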