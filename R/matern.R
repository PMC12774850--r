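#' Matern covariance function
#'
#' Evaluates the stationary Matern covariance between two points a distance
#' `d` apart. Closed forms are used for smoothness 0.5, 1.5 and 2.5; any other
#' smoothness goes through the general modified-Bessel-function expression.
#'
#' @param d Non-negative distance(s) in covariate units (vectorized).
#' @param tau2 Magnitude (marginal variance) of the process, > 0.
#' @param nu Smoothness, > 0. The process is k times mean-square
#'   differentiable when `nu > k`.
#' @param ell Length-scale in covariate units, > 0.
#' @return Covariance value(s) in `(0, tau2]`.
#' @examples
#' matern_cov(0, tau2 = 2)        # equals the magnitude
#' matern_cov(0.7, nu = 1.5)
#' @export
matern_cov <- function(d, tau2 = 1, nu = 1.5, ell = 1) {
  if (!is.numeric(d) || any(!is.finite(d)))
    stop("'d' must be finite and numeric", call. = FALSE)
  if (any(d < 0)) stop("'d' must be non-negative", call. = FALSE)
  check_matern_params(tau2, nu, ell)
  r <- d / ell
  if (nu == 0.5) return(tau2 * exp(-r))
  if (nu == 1.5) {
    a <- sqrt(3) * r
    return(tau2 * (1 + a) * exp(-a))
  }
  if (nu == 2.5) {
    a <- sqrt(5) * r
    return(tau2 * (1 + a + a^2 / 3) * exp(-a))
  }
  # general form; the expression is 0/0 at zero lag, where the limit is tau2
  x <- sqrt(2 * nu) * r
  out <- rep(tau2, length(x))
  pos <- x >= 1e-12
  out[pos] <- tau2 * 2^(1 - nu) / gamma(nu) * x[pos]^nu * besselK(x[pos], nu)
  out
}

check_matern_params <- function(tau2, nu, ell) {
  vals <- c(tau2 = tau2, nu = nu, ell = ell)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("Matern parameters 'tau2', 'nu', 'ell' must be finite and > 0",
         call. = FALSE)
  invisible(TRUE)
}

#' Matern covariance matrix over a set of points
#'
#' Builds the covariance matrix of a Matern Gaussian process at `points`,
#' adding a small diagonal jitter so that the Cholesky factorization succeeds.
#' The jitter starts at `jitter` and is escalated tenfold (up to `1e-4 * tau2`)
#' if the factorization fails; the level actually used is attached as
#' attribute `"jitter"`.
#'
#' @inheritParams matern_cov
#' @param points Numeric vector of locations.
#' @param jitter Initial diagonal jitter (default `1e-8 * tau2`).
#' @return Symmetric positive-definite matrix with attribute `"jitter"`.
#' @export
build_cov_matrix <- function(points, tau2 = 1, nu = 1.5, ell = 1,
                             jitter = 1e-8 * tau2) {
  if (any(!is.finite(points))) stop("'points' must be finite", call. = FALSE)
  if (!is.finite(jitter) || jitter < 0)
    stop("'jitter' must be non-negative", call. = FALSE)
  C0 <- matern_cov(abs(outer(points, points, "-")), tau2, nu, ell)
  C0 <- (C0 + t(C0)) / 2
  j <- max(jitter, 1e-8 * tau2)
  repeat {
    C <- C0 + diag(j, length(points))
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (!is.null(ch)) {
      attr(C, "jitter") <- j
      attr(C, "chol") <- ch
      return(C)
    }
    if (j >= 1e-4 * tau2)
      stop("covariance matrix not positive definite even after jitter ",
           "escalation; grid may be too dense for this length-scale",
           call. = FALSE)
    j <- j * 10
  }
}

#' Draw a Gaussian-process sample at a set of points
#'
#' Draws one or more realizations of a zero-mean Matern GP evaluated at
#' `points`. Uses the current R random-number stream unless `seed` is given.
#'
#' @inheritParams build_cov_matrix
#' @param n_draws Number of independent realizations.
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector (one draw) or matrix with `n_draws` rows.
#' @export
sample_gp <- function(points, tau2 = 1, nu = 1.5, ell = 1,
                      n_draws = 1, seed = NULL, jitter = 1e-8 * tau2) {
  if (!is.null(seed)) set.seed(seed)
  C <- build_cov_matrix(points, tau2, nu, ell, jitter)
  U <- attr(C, "chol")
  Z <- matrix(stats::rnorm(n_draws * length(points)), n_draws)
  out <- Z %*% U
  if (n_draws == 1) drop(out) else out
}
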