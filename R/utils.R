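#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rbinom runif var sd setNames complete.cases
#'   qnorm ppoints logLik vcov coef predict as.formula quantile
#' @importFrom utils combn head write.csv read.csv
NULL

# Derive a reproducible child seed from a master seed and an integer offset.
# Kept strictly below 2^31 so set.seed() always accepts it.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + 7919 * offset) %% 2147483647)
}

# Numerically safe log(sum(exp(x))) with the max-shift trick.
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == round(x) && x >= 0
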