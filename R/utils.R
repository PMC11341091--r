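# Internal helpers shared across modules.

# Clip response rates away from 0/1 before probit transform; the 1/(2n)
# convention keeps d-prime finite and bounded by 2*qnorm(1 - 1/(2n)).
clip_rate <- function(rate, n) {
  stopifnot(all(n > 0))
  pmin(pmax(rate, 1 / (2 * n)), 1 - 1 / (2 * n))
}

# Unit-normalize a vector; error if degenerate.
unitize <- function(v, what = "vector") {
  nv <- sqrt(sum(v^2))
  if (!is.finite(nv) || nv < 1e-12) {
    abort(sprintf("Cannot normalize %s: zero or non-finite norm.", what))
  }
  v / nv
}

# Leading eigenvector of a symmetric matrix with deterministic sign:
# the largest-magnitude element is made positive.
lead_eigvec <- function(S, k = 1L) {
  e <- eigen(S, symmetric = TRUE)
  v <- e$vectors[, k]
  v * sign(v[which.max(abs(v))])
}

# Pooled within-class covariance: average of the two class covariances,
# the "stimulus-independent" covariance entering the decoder.
pooled_cov <- function(A, B) {
  (stats::cov(A) + stats::cov(B)) / 2
}

assert_matrixlike <- function(x, name) {
  x <- as.matrix(x)
  if (!is.numeric(x)) abort(sprintf("`%s` must be numeric.", name))
  x
}

# Draws from N(mu, LL' + diag(psi)) via the factor construction, so the
# generated covariance is exactly the modeled one.
rmvn_factor <- function(n, mu, L, psi) {
  p <- length(mu)
  E <- matrix(rnorm(n * p), n, p) * rep(sqrt(psi), each = n)
  X <- E + matrix(mu, n, p, byrow = TRUE)
  if (!is.null(L) && NCOL(L) > 0) {
    W <- matrix(rnorm(n * NCOL(L)), n, NCOL(L))
    X <- X + W %*% t(L)
  }
  X
}

# Spread integer window counts across bins as evenly as possible
# (first `rem` bins receive the remainder spike).
spread_counts <- function(K, n_bins) {
  base <- K %/% n_bins
  rem <- K %% n_bins
  vapply(seq_len(n_bins), function(b) base + (rem >= b), numeric(length(K)))
}
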