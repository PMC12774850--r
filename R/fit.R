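#' Maximum a posteriori estimate of the log-variance curves
#'
#' Damped Newton-Raphson ascent on the log-posterior with the Hessian
#' replaced by the (negated) Bayesian average-information matrix:
#' `s <- s + alpha BAI^{-1} grad`, with backtracking `alpha in {1, 1/2, ...}`
#' guaranteeing a monotone increase. Converged when the sup-norm of the
#' gradient drops below `tol`.
#'
#' @param data A [gprebe_data()] object (phenotypes on the scaled scale).
#' @param prior A [gp_prior()] object.
#' @param init Initial state (default: zero, the prior mean).
#' @param tol Convergence tolerance on `max(abs(grad))`.
#' @param max_iter Maximum Newton iterations.
#' @return List with `s` (MAP state), `bai` (BAI at the MAP), `converged`,
#'   `iterations`, `log_posterior` (trace over iterations), `grad_norm`.
#' @export
map_estimate <- function(data, prior, init = NULL, tol = 1e-4,
                         max_iter = 100) {
  N <- length(prior$grid)
  s <- if (is.null(init)) numeric(2 * N) else init
  ev <- eval_restricted(s, data, prior, want_grad = TRUE, want_ai = TRUE)
  lp <- ev$loglik + log_prior(s, prior)
  g <- drop(ev$grad) + grad_log_prior(s, prior)
  trace <- lp
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    B <- bai_matrix(ev$ai, prior)
    dir <- drop(chol2inv(attr(B, "chol")) %*% g)
    alpha <- 1
    repeat {
      cand <- s + alpha * dir
      ev_c <- eval_restricted(cand, data, prior, want_grad = TRUE,
                              want_ai = TRUE, soft = TRUE)
      if (isTRUE(ev_c$ok)) {
        lp_c <- ev_c$loglik + log_prior(cand, prior)
        if (is.finite(lp_c) && lp_c > lp) break
      }
      alpha <- alpha / 2
      if (alpha < 2^-30) { lp_c <- NA; break }
    }
    if (!is.finite(lp_c)) break  # no ascent possible: numerically stationary
    s <- cand; lp <- lp_c; ev <- ev_c
    g <- drop(ev$grad) + grad_log_prior(s, prior)
    trace <- c(trace, lp)
  }
  if (max(abs(g)) < tol) converged <- TRUE
  if (!converged)
    warning("MAP search stopped after ", it, " iterations with gradient ",
            "sup-norm ", format(max(abs(g)), digits = 3),
            "; returning the last state")
  list(s = s, bai = bai_matrix(ev$ai, prior), converged = converged,
       iterations = it, log_posterior = trace, grad_norm = max(abs(g)))
}

#' Summarize an MCMC chain of log-variance states
#'
#' Transforms each sampled state to variance curves at the grid points
#' (`sigma^2 = exp(s)`, rescaled to original units by `factor^2`), computes
#' heritability per sample, and reduces to pointwise posterior means and
#' 2.5/97.5 percent quantiles. Bands are of the heritability itself, computed
#' per sample before summarizing.
#'
#' @param chain Matrix of sampled states, one row per draw, columns
#'   `[s_E; s_G]`.
#' @param grid Grid points the states refer to.
#' @param factor Scale factor from [scale_data()] (variances multiply by
#'   `factor^2`); default 1.
#' @return Data frame with columns `t`, `sigmaE2_mean`, `sigmaE2_lo`,
#'   `sigmaE2_hi`, `sigmaG2_mean`, `sigmaG2_lo`, `sigmaG2_hi`, `h2_mean`,
#'   `h2_lo`, `h2_hi`.
#' @export
summarize_chain <- function(chain, grid, factor = 1) {
  chain <- as.matrix(chain)
  if (nrow(chain) < 1) stop("'chain' is empty", call. = FALSE)
  N <- length(grid)
  if (ncol(chain) != 2 * N)
    stop("'chain' must have 2 * length(grid) columns", call. = FALSE)
  sE2 <- exp(chain[, seq_len(N), drop = FALSE]) * factor^2
  sG2 <- exp(chain[, N + seq_len(N), drop = FALSE]) * factor^2
  h2 <- sG2 / (sE2 + sG2)
  qs <- function(m) apply(m, 2, stats::quantile, probs = c(0.025, 0.975),
                          names = FALSE)
  qE <- qs(sE2); qG <- qs(sG2); qh <- qs(h2)
  data.frame(t = grid,
             sigmaE2_mean = colMeans(sE2), sigmaE2_lo = qE[1, ],
             sigmaE2_hi = qE[2, ],
             sigmaG2_mean = colMeans(sG2), sigmaG2_lo = qG[1, ],
             sigmaG2_hi = qG[2, ],
             h2_mean = colMeans(h2), h2_lo = qh[1, ], h2_hi = qh[2, ])
}

#' Fit dynamic variance components and heritability curves
#'
#' End-to-end posterior estimation: scales the phenotypes to sample variance
#' 2, builds the computational grid and Matern smoothing prior, finds the MAP
#' state by average-information Newton ascent, freezes the inverse BAI matrix
#' at the MAP as a global MALA preconditioner, runs the preconditioned MALA
#' chain, and summarizes it into pointwise posterior means and 95% credible
#' bands for the residual variance, genetic variance and narrow-sense
#' heritability curves in original data units.
#'
#' @param y Phenotype vector, or a [gprebe_data()] object (then `t`, `G`, `X`
#'   are ignored).
#' @param t Covariate vector.
#' @param G Relationship matrix.
#' @param X Optional fixed-effect design (default: intercept).
#' @param grid_size Number of grid points (default 50).
#' @param magnitude,smoothness,lengthscale Matern prior hyperparameters;
#'   `lengthscale = "range"` uses the observed covariate range.
#' @param iterations Total MALA iterations (default 5000).
#' @param burnin Burn-in fraction discarded (default 0.5).
#' @param step_size Initial MALA step size (adapted during burn-in).
#' @param target_accept Acceptance rate targeted by the adaptation.
#' @param seed Optional integer seed making the whole fit reproducible.
#' @param map_tol,map_maxit MAP search tolerance and iteration cap.
#' @param jitter Initial diagonal jitter for the prior covariance.
#' @return Object of class `gprebe`: list with `summary` (the
#'   [summarize_chain()] data frame in original units), `chain` (kept
#'   post-burn-in states), `map` (MAP results), `grid`, `prior`,
#'   `scale_factor`, `accept_rate`, `step_size`, `log_posterior_trace`,
#'   `config`.
#' @examples
#' rep <- sim_gp_replicate(n = 120, seed = 1)
#' fit <- gprebe(rep$y, rep$t, rep$G, iterations = 400, seed = 1)
#' head(fit$summary)
#' @export
gprebe <- function(y, t = NULL, G = NULL, X = NULL, grid_size = 50,
                   magnitude = 1, smoothness = 1.5, lengthscale = "range",
                   iterations = 5000, burnin = 0.5, step_size = 0.1,
                   target_accept = 0.574, seed = NULL, map_tol = 1e-4,
                   map_maxit = 100, jitter = 1e-8 * magnitude) {
  data <- if (inherits(y, "gprebe_data")) y else gprebe_data(y, t, G, X)
  if (!is.null(seed)) set.seed(seed)
  sc <- scale_data(data$y)
  sdata <- data
  sdata$y <- sc$y
  grid <- make_grid(data$t, grid_size)
  prior <- gp_prior(grid, data$t, magnitude, smoothness, lengthscale, jitter)

  map <- map_estimate(sdata, prior, tol = map_tol, max_iter = map_maxit)
  A <- chol2inv(attr(map$bai, "chol"))
  A <- (A + t(A)) / 2

  run <- mala(log_target = function(s) {
                ev <- eval_restricted(s, sdata, prior, soft = TRUE)
                if (!isTRUE(ev$ok)) return(-Inf)
                ev$loglik + log_prior(s, prior)
              },
              grad_target = function(s)
                drop(eval_restricted(s, sdata, prior,
                                     want_grad = TRUE)$grad) +
                  grad_log_prior(s, prior),
              init = map$s, iterations = iterations, burnin = burnin,
              step_size = step_size, target_accept = target_accept,
              precond = A)

  structure(list(summary = summarize_chain(run$samples, grid, sc$factor),
                 chain = run$samples, map = map, grid = grid, prior = prior,
                 scale_factor = sc$factor, accept_rate = run$accept_rate,
                 step_size = run$step_size,
                 log_posterior_trace = run$log_target_trace,
                 data = data,
                 config = list(grid_size = grid_size, magnitude = magnitude,
                               smoothness = smoothness,
                               lengthscale = prior$lengthscale,
                               iterations = iterations, burnin = burnin,
                               step_size = step_size,
                               target_accept = target_accept, seed = seed,
                               map_tol = map_tol, map_maxit = map_maxit,
                               jitter = prior$jitter)),
            class = "gprebe")
}

#' @export
print.gprebe <- function(x, ...) {
  cat("Dynamic variance-component fit (GP restricted Bayesian estimation)\n")
  cat(sprintf("  n = %d, grid = %d points on [%.4g, %.4g]\n",
              length(x$data$y), length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf("  MALA: %d iterations, acceptance rate %.2f, step size %.3g\n",
              x$config$iterations, x$accept_rate, x$step_size))
  cat(sprintf("  MAP %s in %d Newton iterations (grad sup-norm %.2g)\n",
              if (x$map$converged) "converged" else "NOT converged",
              x$map$iterations, x$map$grad_norm))
  h <- x$summary$h2_mean
  cat(sprintf("  posterior-mean heritability: %.2f to %.2f across the grid\n",
              min(h), max(h)))
  invisible(x)
}

#' Interpolate posterior-mean variance curves to arbitrary covariate points
#'
#' Carries the posterior-mean curves from the grid to `points` with the same
#' GP linear interpolation used inside the model; tiny negative values that
#' interpolation of the variance scale can produce are clamped to a small
#' positive floor.
#'
#' @param fit A [gprebe()] fit.
#' @param points Covariate points (clamped to the grid range).
#' @return Data frame with `t`, `sigmaE2`, `sigmaG2`, `h2`.
#' @export
interp_curves <- function(fit, points) {
  Wn <- interp_weights(fit$grid, points, fit$prior$magnitude,
                       fit$prior$smoothness, fit$prior$lengthscale,
                       fit$prior$jitter)
  e2 <- pmax(drop(Wn %*% fit$summary$sigmaE2_mean), 1e-12)
  g2 <- pmax(drop(Wn %*% fit$summary$sigmaG2_mean), 1e-12)
  data.frame(t = points, sigmaE2 = e2, sigmaG2 = g2, h2 = g2 / (e2 + g2))
}

#' Plot fitted variance and heritability curves
#'
#' @param x A [gprebe()] fit.
#' @param truth Optional list with elements `t`, `sigma_e2`, `sigma_g2` to
#'   overlay ground-truth curves (e.g. from a simulation replicate).
#' @param ... Unused.
#' @export
plot.gprebe <- function(x, truth = NULL, ...) {
  s <- x$summary
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  panel <- function(m, lo, hi, ylab, tr) {
    ylim <- range(lo, hi, tr)
    plot(s$t, m, type = "l", ylim = ylim, xlab = "covariate", ylab = ylab)
    graphics::lines(s$t, lo, lty = 2)
    graphics::lines(s$t, hi, lty = 2)
    if (!is.null(tr)) graphics::points(truth$t, tr, col = "red", cex = 0.3)
  }
  panel(s$sigmaE2_mean, s$sigmaE2_lo, s$sigmaE2_hi,
        expression(sigma[E]^2 * (t)), truth$sigma_e2)
  panel(s$sigmaG2_mean, s$sigmaG2_lo, s$sigmaG2_hi,
        expression(sigma[G]^2 * (t)), truth$sigma_g2)
  h_tr <- if (is.null(truth)) NULL else
    truth$sigma_g2 / (truth$sigma_g2 + truth$sigma_e2)
  panel(s$h2_mean, s$h2_lo, s$h2_hi, expression(h^2 * (t)), h_tr)
  invisible(x)
}
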