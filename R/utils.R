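#' Derive a stream-specific random seed from a master seed
#'
#' All stochastic functions in the package draw their randomness from a single
#' master seed through this splitting scheme, so that an entire pipeline run is
#' reproducible from one integer while distinct stages get decorrelated
#' streams.
#'
#' @param seed master seed (single integer).
#' @param stream stream index (non-negative integer), one per consumer.
#' @return An integer in `[0, 2^31 - 1)` suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(1, 0)
#' derive_seed(1, 1)
derive_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647               # 2^31 - 1, Mersenne prime
  s <- (abs(as.numeric(seed)) %% m)
  # two rounds of a Lehmer-style multiplicative mix keep streams decorrelated
  s <- (s * 48271 + stream * 16807 + 12345) %% m
  s <- (s * 48271 + 1) %% m
  as.integer(s)
}

# z-standardize columns of a matrix with sample (n-1) SD; zero-variance
# columns map to all-zero columns (kept, flagged) rather than NaN.
standardize_columns <- function(X, center = NULL, scale = NULL) {
  X <- as.matrix(X)
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) scale <- apply(X, 2L, sd)
  ok <- is.finite(scale) & scale > 0
  Z <- sweep(X, 2L, center, "-")
  Z[, ok] <- sweep(Z[, ok, drop = FALSE], 2L, scale[ok], "/")
  Z[, !ok] <- 0
  list(Z = Z, center = center, scale = scale, nonconstant = ok)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
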