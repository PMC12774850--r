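test_that("assemble_K reproduces the element-wise covariance statements", {
  # identity weights, zero state, G = I -> K = 2 I
  W <- diag(4)
  out <- assemble_K(numeric(8), W, diag(4))
  expect_equal(out$K, 2 * diag(4))
  # constant genetic log-variance log 4, zero residual -> K = 4 G + I
  set.seed(2)
  G <- sim_relationship(4)
  out <- assemble_K(c(rep(0, 4), rep(log(4), 4)), W, G)
  expect_equal(out$K, 4 * G + diag(4), tolerance = 1e-12)
  # random state against the double-loop oracle
  inst <- make_instance(8, 5, seed = 21)
  s <- inst$s; W <- inst$prior$W; G <- inst$data$G
  out <- assemble_K(s, W, G)
  sigG <- exp(0.5 * drop(W %*% s[6:10]))
  sigE2 <- exp(drop(W %*% s[1:5]))
  oracle <- matrix(NA, 8, 8)
  for (i in 1:8) for (j in 1:8)
    oracle[i, j] <- sigG[i] * sigG[j] * G[i, j] + (i == j) * sigE2[i]
  expect_equal(out$K, oracle, tolerance = 1e-12)
  expect_error(assemble_K(c(rep(0, 5), rep(200, 5)), W, G), "overflow")
})

test_that("restricted likelihood has its closed form for K = I and ignores fixed effects", {
  y <- c(0.3, -1.2, 2.5)
  d <- gprebe_data(y, 1:3, diag(3))
  expect_equal(restricted_loglik(d, diag(3)),
               -0.5 * log(3) - 0.5 * sum((y - mean(y))^2))
  # exact invariance under y -> y + X b
  inst <- make_instance(12, 4, seed = 31)
  K <- assemble_K(inst$s, inst$prior$W, inst$data$G)$K
  d2 <- inst$data
  d2$y <- d2$y + drop(d2$X %*% 3.7)
  expect_equal(restricted_loglik(inst$data, K), restricted_loglik(d2, K),
               tolerance = 1e-10)
  expect_error(restricted_loglik(d, matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)),
               "positive definite")
})

test_that("restricted-likelihood differences equal the error-contrast Gaussian oracle", {
  for (seed in 1:6) {
    inst <- make_instance(12, 4, seed = 40 + seed)
    s1 <- inst$s
    s2 <- rnorm(8, 0, 0.3)
    K1 <- assemble_K(s1, inst$prior$W, inst$data$G)$K
    K2 <- assemble_K(s2, inst$prior$W, inst$data$G)$K
    d <- inst$data
    lhs <- restricted_loglik(d, K1) - restricted_loglik(d, K2)
    rhs <- contrast_loglik(d$y, d$X, K1) - contrast_loglik(d$y, d$X, K2)
    expect_equal(lhs, rhs, tolerance = 1e-8)
  }
})

test_that("log-posterior is the sum of its independently computed parts", {
  inst <- make_instance(10, 5, seed = 55)
  K <- assemble_K(inst$s, inst$prior$W, inst$data$G)$K
  expect_equal(log_posterior(inst$s, inst$data, inst$prior),
               restricted_loglik(inst$data, K) +
                 log_prior(inst$s, inst$prior),
               tolerance = 1e-12)
})

test_that("gradient matches central finite differences across many random instances", {
  set.seed(99)
  sizes <- cbind(n = sample(5:30, 20, replace = TRUE),
                 N = sample(3:10, 20, replace = TRUE))
  for (i in seq_len(20)) {
    inst <- make_instance(sizes[i, "n"], sizes[i, "N"], seed = 100 + i)
    g <- grad_log_posterior(inst$s, inst$data, inst$prior)
    fd <- fd_gradient(function(s) log_posterior(s, inst$data, inst$prior),
                      inst$s)
    expect_lt(max(abs(g - fd)), 1e-4 * (1 + max(abs(g))))
  }
})

test_that("genetic and residual score blocks are symmetric when G = I and the blocks coincide", {
  # with G = I, sigma_G^2 = sigma_E^2 and an intercept-only design, swapping
  # the two blocks' roles leaves the likelihood score unchanged
  set.seed(7)
  n <- 12; N <- 4
  t <- sort(runif(n, -1, 1))
  d <- gprebe_data(rnorm(n), t, diag(n))
  pr <- gp_prior(make_grid(t, N), t)
  s <- rep(rnorm(N, 0, 0.2), 2)  # s_E = s_G
  # strip the prior part to isolate the likelihood score
  g <- grad_log_posterior(s, d, pr) - gprebe:::grad_log_prior(s, pr)
  expect_equal(g[1:N] + g[(N + 1):(2 * N)], 2 * g[1:N], tolerance = 1e-8)
})

test_that("projection annihilates the design and AI is symmetric PSD", {
  for (seed in c(1, 2)) {
    inst <- make_instance(10, 4, seed = 200 + seed)
    K <- assemble_K(inst$s, inst$prior$W, inst$data$G)$K
    P <- projection_P(inst$data$X, K)
    expect_lt(max(abs(P %*% inst$data$X)), 1e-10)
    expect_equal(P, t(P), tolerance = 1e-12)
    ai <- ai_matrix(inst$s, inst$data, inst$prior)
    expect_equal(ai, t(ai), tolerance = 1e-12)
    ev <- eigen(ai, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10 * max(abs(ev)))
  }
})

test_that("AI matches dense quadratic-form oracles", {
  inst <- make_instance(8, 3, seed = 77)
  ai <- ai_matrix(inst$s, inst$data, inst$prior)
  K <- assemble_K(inst$s, inst$prior$W, inst$data$G)$K
  P <- projection_P(inst$data$X, K)
  dKs <- dense_dK(inst$s, inst$prior$W, inst$data$G)
  Py <- drop(P %*% inst$data$y)
  oracle <- matrix(NA, 6, 6)
  for (i in 1:6) for (j in 1:6)
    oracle[i, j] <- 0.5 * Py %*% dKs[[i]] %*% P %*% dKs[[j]] %*% Py
  oracle <- (oracle + t(oracle)) / 2
  expect_equal(ai, oracle, tolerance = 1e-10)
})

test_that("BAI adds the prior precision and stays PD (Weyl bound)", {
  inst <- make_instance(10, 5, seed = 301)
  pr <- inst$prior
  blk <- rbind(cbind(pr$C_inv, matrix(0, 5, 5)),
               cbind(matrix(0, 5, 5), pr$C_inv))
  # AI = 0 -> BAI is exactly the prior precision
  b0 <- bai_matrix(matrix(0, 10, 10), pr)
  expect_equal(unclass(b0), blk, tolerance = 1e-12, ignore_attr = TRUE)
  ai <- ai_matrix(inst$s, inst$data, inst$prior)
  b <- bai_matrix(ai, pr)
  expect_equal(unclass(b), t(unclass(b)), ignore_attr = TRUE)
  ev_b <- eigen(b, symmetric = TRUE, only.values = TRUE)$values
  ev_p <- eigen(blk, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev_b), min(ev_p) - 1e-10)
})
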