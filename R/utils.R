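#' @useDynLib swarmdx, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm sd setNames
#' @importFrom utils head write.csv read.csv capture.output
NULL

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL runs `code` on the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Stable per-stage seed derivation: fold the stage name into the master seed
# so each pipeline stage has its own reproducible stream. Result < 2^31.
derive_seed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 1000000007
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647) + 1L
}

# Round half-up to `digits` decimals (base round() is half-to-even; reported
# tables use the conventional half-up at two decimals).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

clamp <- function(x, lower, upper) pmin(pmax(x, lower), upper)

sigmoid <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a
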