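test_that("simulated relationship matrices have unit diagonal and are PSD", {
  G <- sim_relationship(50, seed = 3)
  expect_equal(diag(G), rep(1, 50))
  expect_true(all(G > 0 & G <= 1))
  expect_equal(G, t(G))
  expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
            -1e-10)
  # two individuals: entry is exactly exp(-rate * |u1 - u2|)
  set.seed(8)
  u <- runif(2)
  set.seed(8)
  G2 <- sim_relationship(2, rate = 200)
  expect_equal(G2[1, 2], exp(-200 * abs(u[1] - u[2])))
})

test_that("GP-generator replicates are reproducible and carry positive truths", {
  r1 <- sim_gp_replicate(n = 40, seed = 5)
  r2 <- sim_gp_replicate(n = 40, seed = 5)
  expect_identical(r1$y, r2$y)
  expect_identical(r1$sigma_g2, r2$sigma_g2)
  expect_true(all(r1$sigma_g2 > 0 & r1$sigma_e2 > 0))
  expect_true(all(r1$t >= -1 & r1$t <= 1))
  expect_length(r1$y, 40)
})

test_that("GP generator's phenotype covariance matches its target (Monte Carlo)", {
  # unit curves on a fixed (t, G) so that cov(y) = G + I
  n <- 5; draws <- 2000
  base <- sim_gp_replicate(n = n, grid_size = 5, seed = 101)
  unit <- list(s_e = rep(0, 5), s_g = rep(0, 5))
  set.seed(66)
  Y <- t(replicate(draws, {
    rep <- sim_gp_replicate(grid_size = 5, s_curves = unit,
                            t = base$t, G = base$G)
    rep$y - rep$r
  }))
  K_target <- base$G + diag(n)
  emp <- cov(Y)
  se <- sqrt((diag(K_target) %o% diag(K_target) + K_target^2) / draws)
  expect_true(all(abs(emp - K_target) < 3.5 * se))
  # marginal variances: var(y_i - r) = G_ii sigma_g2 + sigma_e2 = 2
  expect_true(all(abs(diag(emp) - 2) < 3.5 * sqrt(2 * 4 / draws)))
  # pooled standardized draws look Gaussian
  expect_gt(shapiro.test(as.vector(scale(Y))[1:5000])$p.value, 0.01)
})

test_that("RRM generator matches the Kronecker-product construction", {
  set.seed(12)
  n <- 6
  rep <- sim_rrm_replicate(n = n, order = 1, seed = 77)
  # replay the draws to recover the factors
  set.seed(77)
  t <- runif(n, -1, 1)
  u <- runif(n)
  G <- exp(-200 * abs(outer(u, u, "-")))
  Lg <- matrix(0, 2, 2); Le <- matrix(0, 2, 2)
  low <- lower.tri(Lg, diag = TRUE)
  Lg[low] <- runif(3, -1, 1)
  Le[low] <- runif(3, -1, 1)
  expect_identical(rep$t, t)
  expect_identical(rep$G, G)
  Sg <- tcrossprod(Lg); Se <- tcrossprod(Le)
  # dense Phi (G (x) Sigma_G) Phi' + Phi (I (x) Sigma_E) Phi'
  Phi <- matrix(0, n, 2 * n)
  for (i in 1:n) Phi[i, 2 * i - c(1, 0)] <- c(1, t[i])
  K_dense <- Phi %*% (G %x% Sg) %*% t(Phi) + Phi %*% (diag(n) %x% Se) %*% t(Phi)
  expect_equal(diag(K_dense), rep$sigma_g2 + rep$sigma_e2, tolerance = 1e-12)
  # per-pair formula used by the generator
  K_pair <- matrix(NA, n, n)
  phi <- cbind(1, t)
  for (i in 1:n) for (j in 1:n)
    K_pair[i, j] <- G[i, j] * phi[i, ] %*% Sg %*% phi[j, ] +
      (i == j) * phi[i, ] %*% Se %*% phi[i, ]
  expect_equal(K_dense, K_pair, tolerance = 1e-12)
  expect_equal(rep$sigma_g2, diag(Phi %*% (G %x% Sg) %*% t(Phi)),
               tolerance = 1e-12)
})

test_that("first-order RRM truths are exact quadratics in the covariate", {
  rep <- sim_rrm_replicate(n = 60, order = 1, seed = 9)
  for (curve in list(rep$sigma_g2, rep$sigma_e2)) {
    fit <- lm(curve ~ poly(rep$t, 2, raw = TRUE))
    expect_lt(max(abs(residuals(fit))), 1e-10)
  }
  r2 <- sim_rrm_replicate(n = 60, order = 2, seed = 9)
  fit4 <- lm(r2$sigma_g2 ~ poly(r2$t, 4, raw = TRUE))
  expect_lt(max(abs(residuals(fit4))), 1e-10)
  expect_identical(sim_rrm_replicate(n = 20, order = 2, seed = 4)$y,
                   sim_rrm_replicate(n = 20, order = 2, seed = 4)$y)
})

test_that("NMSE satisfies its defining identities", {
  truth <- c(1, 2)
  expect_equal(nmse(truth, truth), 0)
  expect_equal(nmse(c(0, 0), truth), 1)
  expect_equal(nmse(c(2, 2), truth), 1 / 5)
  # scale awareness: nmse(c * truth, truth) = (c - 1)^2 exactly
  set.seed(2)
  tr <- runif(20, 0.5, 3)
  for (cc in c(0.3, 1, 2.5)) expect_equal(nmse(cc * tr, tr), (cc - 1)^2)
  expect_error(nmse(1:3, 1:4), "equal length")
  expect_error(nmse(c(1, 1), c(0, 0)), "identically zero")
})

test_that("longer chains do not worsen median estimation accuracy", {
  med <- sapply(c(300, 3000), function(iters) {
    per_seed <- sapply(1:5, function(sd) {
      rep <- sim_gp_replicate(n = 250, seed = 10 * sd + 1)
      f <- gprebe(rep$y, rep$t, rep$G, iterations = iters, seed = 10 * sd + 2)
      est <- interp_curves(f, rep$t)
      c(nmse(est$sigmaG2, rep$sigma_g2), nmse(est$sigmaE2, rep$sigma_e2))
    })
    apply(per_seed, 1, median)
  })
  expect_lte(med[1, 2], med[1, 1])
  expect_lte(med[2, 2], med[2, 1])
})

test_that("benchmark reduces per-replicate errors to median and MAD", {
  # known-truth stub estimator: all medians zero
  stub <- function(rep) list(sigma_e2 = rep$sigma_e2,
                             sigma_g2 = rep$sigma_g2)
  b <- run_benchmark("gp", n = 20, replicates = 3, seed = 1,
                     estimator = stub)
  expect_equal(b$median_g, 0)
  expect_equal(b$median_e, 0)
  expect_equal(b$mad_g, 0)
  # single replicate: median is that replicate's NMSE, MAD = 0
  half <- function(rep) list(sigma_e2 = 0.5 * rep$sigma_e2,
                             sigma_g2 = 0.5 * rep$sigma_g2)
  b1 <- run_benchmark("rrm1", n = 20, replicates = 1, seed = 2,
                      estimator = half)
  expect_equal(b1$median_g, 0.25)
  expect_equal(b1$mad_e, 0)
  # failures are excluded with a warning
  flaky <- local({
    k <- 0
    function(rep) {
      k <<- k + 1
      if (k == 2) stop("boom")
      stub(rep)
    }
  })
  expect_warning(b2 <- run_benchmark("gp", n = 20, replicates = 3, seed = 3,
                                     estimator = flaky), "excluded")
  expect_equal(b2$failures, 1L)
  expect_equal(nrow(b2$table), 2L)
})
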