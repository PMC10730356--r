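#' @useDynLib spatzone, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rpois rbinom rlnorm median sd cor quantile
#'   glm glm.fit binomial predict coef pnorm qlogis plogis setNames aggregate
#' @importFrom utils combn head read.csv write.csv
NULL

ZONES <- c("stroma", "front", "core")

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a stream of child seeds from a parent seed, each below 2^31.
# Deterministic, collision-unlikely integer hash (splitmix-style on doubles).
derive_seed <- function(seed, index) {
  x <- (as.double(seed) * 48271 + as.double(index) * 16807 + 12345) %% 2147483647
  as.integer(x %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
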