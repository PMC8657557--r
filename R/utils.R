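#' @importFrom methods new validObject is slot setClass setGeneric setMethod setValidity show
#' @importFrom stats rbeta rbinom rnorm rpois runif dbeta pbeta qbeta pt sd
#' @importFrom utils read.csv read.delim write.csv write.table
NULL

## Evaluate `expr` under a fixed RNG state without disturbing the caller's
## stream. All simulation entry points funnel through this so that a seed
## fully determines their output.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

## row variance with explicit denominator n-1; matrix must have >= 2 columns
row_var <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
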