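# internal helpers shared across modules

# Deterministic 32-bit sub-seed from a master seed and a tag, so that every
# randomized stage draws from its own stream while staying reproducible from
# one user-facing seed.
derive_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 1000000007
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Cholesky-based multivariate normal draw; rows are observations.
rmvn <- function(n, mu, sigma) {
  p <- length(mu)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- eigen(sigma, symmetric = TRUE)
    if (min(ev$values) < -1e-8 * max(abs(ev$values)))
      stopf("covariance matrix is not positive semi-definite")
    ch <- t(ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors)))
  }
  matrix(stats::rnorm(n * p), n, p) %*% ch + rep(mu, each = n)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
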