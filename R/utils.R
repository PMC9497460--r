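#' Derive a child seed from a parent seed and a module key
#'
#' All stochastic stages derive their own seed from one global seed by mixing
#' in a string key, so stages are reproducible in isolation and independent
#' of one another. The result is always in [1, 2^31 - 2].
#'
#' @param seed integer parent seed.
#' @param key character key naming the consumer (e.g. "phantom", "train").
#' @return an integer seed.
#' @export
deriveSeed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  h <- as.double(seed %% 2147483647)
  for (b in utf8ToInt(key)) h <- (h * 131 + b) %% 2147483647
  as.integer(h %% 2147483646 + 1)
}

# Reflect 1-based indices into [1, n] (mirror padding without edge repeat,
# "abc|cb..."); degenerates to clamping when n == 1.
reflectIndex <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * (n - 1L)
  m <- (idx - 1L) %% period
  m <- ifelse(m < 0L, m + period, m)
  as.integer(ifelse(m < n, m + 1L, period - m + 1L))
}

# Row-wise argmax with ties broken toward the lowest column index.
argmaxRows <- function(m) max.col(m, ties.method = "first")

# round-half-up (R's round() is banker's rounding)
roundHalfUp <- function(x) floor(x + 0.5)

asCount <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x != floor(x))
    stop(sprintf("'%s' must be a single non-negative integer", name))
  as.integer(x)
}

# per-voxel class weights: 1 for background, fgWeight for classes 1-3
classWeights <- function(target, fgWeight) {
  w <- array(1, dim = dim(target))
  w[target > 0] <- fgWeight
  w
}
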