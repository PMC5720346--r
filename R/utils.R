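#' @importFrom stats rnorm runif rchisq rt rgamma var sd cor cor.test
#' @importFrom stats lm.fit model.matrix pt pchisq phyper p.adjust t.test
#' @importFrom stats uniroot quantile setNames
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' All randomness in the package flows from a single integer seed; substreams
#' for independent stages (covariate draws, gene variances, noise, resampling)
#' are derived deterministically with an integer hash so that any stage can be
#' regenerated on its own. Arithmetic stays below 2^53 so the result is exact
#' on IEEE doubles and identical across platforms.
#'
#' @param seed master integer seed.
#' @param index substream index (any non-negative integer).
#' @return an integer in `[0, 2^31 - 1)` suitable for [set.seed()].
#' @export
splitSeed <- function(seed, index) {
  a <- abs(as.numeric(seed)) %% 2147483647
  h <- (a * 69069 + as.numeric(index) * 1234567 + 101) %% 2147483647
  h <- (h * 69069 + 7) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a local RNG state; the caller's .Random.seed is
# restored afterwards, so resampling-based selection does not perturb
# simulation reproducibility.
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# p-values are never reported as exactly zero
floorPValues <- function(p) pmax(p, .Machine$double.xmin)

# format a numeric column to 9 significant digits for deterministic output
fmtNum <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.9g", x))
}
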