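# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately naive dense algebra, kept separate from the
# package's computational path.

# small correlated dataset with random log-variance state
make_instance <- function(n, N, seed) {
  set.seed(seed)
  t <- sort(runif(n, -1, 1))
  G <- sim_relationship(n)
  y <- rnorm(n, 1)
  data <- gprebe_data(y, t, G)
  prior <- gp_prior(make_grid(t, N), t)
  s <- rnorm(2 * N, 0, 0.3)
  list(data = data, prior = prior, s = s, n = n, N = N)
}

# central finite differences of a scalar function
fd_gradient <- function(f, x, h = 1e-5) {
  sapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  })
}

# error-contrast REML oracle: Gaussian log-density of B'y under N(0, B'KB),
# B an orthonormal basis of the null space of X'
contrast_loglik <- function(y, X, K) {
  Q <- qr.Q(qr(X), complete = TRUE)
  B <- Q[, (ncol(X) + 1):ncol(Q), drop = FALSE]
  z <- drop(crossprod(B, y))
  S <- crossprod(B, K %*% B)
  -0.5 * determinant(S)$modulus[1] -
    0.5 * sum(z * solve(S, z)) - 0.5 * length(z) * log(2 * pi)
}

# dense REML projection matrix
projection_P <- function(X, K) {
  Kinv <- solve(K)
  Kinv - Kinv %*% X %*% solve(crossprod(X, Kinv %*% X), t(X) %*% Kinv)
}

# dense dK/ds_j matrices at a state, from the covariance statements of the
# model (double-loop construction, independent of the package internals)
dense_dK <- function(s, W, G) {
  N <- ncol(W); n <- nrow(W)
  sigG <- exp(0.5 * drop(W %*% s[(N + 1):(2 * N)]))
  sigE2 <- exp(drop(W %*% s[1:N]))
  DG <- diag(sigG, n)
  out <- vector("list", 2 * N)
  for (j in 1:N) out[[j]] <- diag(sigE2 * W[, j], n)
  for (j in 1:N) {
    Dj <- diag(0.5 * sigG * W[, j], n)
    out[[N + j]] <- Dj %*% G %*% DG + DG %*% G %*% Dj
  }
  out
}
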