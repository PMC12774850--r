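#' Uniform computational grid over the observed covariate range
#'
#' The log-variance curves are represented by their values at `n_grid`
#' uniformly spaced points spanning exactly the observed covariate range;
#' the grid size controls the number of parameters sampled by the MCMC.
#'
#' @param t Observed covariate values.
#' @param n_grid Number of grid points (>= 3, default 50).
#' @return Strictly increasing numeric vector of length `n_grid` whose first
#'   and last elements equal `min(t)` and `max(t)`.
#' @export
make_grid <- function(t, n_grid = 50) {
  if (any(!is.finite(t))) stop("'t' must be finite", call. = FALSE)
  if (n_grid < 3) stop("'n_grid' must be at least 3", call. = FALSE)
  r <- range(t)
  if (r[1] == r[2])
    stop("covariate has zero range; a dynamic model needs spread in t",
         call. = FALSE)
  seq(r[1], r[2], length.out = n_grid)
}

#' Gaussian-process interpolation weights from grid to target points
#'
#' Interpolating a GP with grid covariance `C_g` from its values `f_g` at the
#' grid points to a point `t*` is the linear map `f(t*) = c*' C_g^{-1} f_g`,
#' where `c*` holds the covariances between `t*` and the grid. This returns
#' the full weight matrix `W` (one row per target) so that `W %*% f_g` gives
#' the conditional mean at all targets at once. The diagonal jitter on `C_g`
#' is treated as a nugget of the process and therefore also enters the
#' cross-covariance at zero distance, so a target coinciding with a grid
#' point reproduces that knot exactly. Targets outside the grid range are
#' clamped to the nearest endpoint with a warning.
#'
#' @param grid Strictly increasing grid points (see [make_grid()]).
#' @param targets Points to interpolate to.
#' @inheritParams build_cov_matrix
#' @return `length(targets)` x `length(grid)` weight matrix.
#' @export
interp_weights <- function(grid, targets, tau2 = 1, nu = 1.5, ell = 1,
                           jitter = 1e-8 * tau2) {
  if (any(!is.finite(targets))) stop("'targets' must be finite", call. = FALSE)
  lo <- min(grid); hi <- max(grid)
  if (any(targets < lo | targets > hi)) {
    warning("targets outside the grid range were clamped to the endpoints")
    targets <- pmin(pmax(targets, lo), hi)
  }
  C <- build_cov_matrix(grid, tau2, nu, ell, jitter)
  Cinv <- chol2inv(attr(C, "chol"))
  D <- abs(outer(targets, grid, "-"))
  Cc <- matern_cov(D, tau2, nu, ell) + attr(C, "jitter") * (D == 0)
  Cc %*% Cinv
}

#' Smoothing-prior structure for the log-variance curves
#'
#' Precomputes everything the posterior needs from the Matern prior: the grid
#' covariance matrix and its inverse, and the interpolation weight matrix `W`
#' mapping grid values of a curve to the measurement points. The prior for the
#' stacked state `s = [s_E; s_G]` is two independent zero-mean Gaussians with
#' covariance `C`, so its (constant) Hessian is `-blockdiag(C^{-1}, C^{-1})`.
#'
#' The default length-scale (`ell = "range"`) is the distance between the
#' largest and smallest covariate values, which yields fairly regular curves
#' while leaving room for local variation.
#'
#' @param grid Grid points (see [make_grid()]).
#' @param targets Measurement covariate values.
#' @param magnitude Matern magnitude tau^2 (default 1).
#' @param smoothness Matern smoothness nu (default 1.5).
#' @param lengthscale Matern length-scale, or `"range"` for the grid span.
#' @param jitter Initial diagonal jitter for the grid covariance.
#' @return Object of class `gp_prior`: list with elements `grid`, `C`,
#'   `C_chol`, `C_inv`, `W`, `magnitude`, `smoothness`, `lengthscale`,
#'   `jitter`.
#' @export
gp_prior <- function(grid, targets, magnitude = 1, smoothness = 1.5,
                     lengthscale = "range", jitter = 1e-8 * magnitude) {
  if (identical(lengthscale, "range")) lengthscale <- diff(range(grid))
  check_matern_params(magnitude, smoothness, lengthscale)
  C <- build_cov_matrix(grid, magnitude, smoothness, lengthscale, jitter)
  ch <- attr(C, "chol")
  W <- interp_weights(grid, targets, magnitude, smoothness, lengthscale,
                      jitter)
  structure(list(grid = grid, C = C, C_chol = ch, C_inv = chol2inv(ch),
                 W = W, magnitude = magnitude, smoothness = smoothness,
                 lengthscale = lengthscale, jitter = attr(C, "jitter")),
            class = "gp_prior")
}

#' @export
print.gp_prior <- function(x, ...) {
  cat("Matern GP smoothing prior\n")
  cat(sprintf("  grid: %d points on [%.4g, %.4g]\n", length(x$grid),
              min(x$grid), max(x$grid)))
  cat(sprintf("  magnitude %.3g, smoothness %.3g, length-scale %.3g\n",
              x$magnitude, x$smoothness, x$lengthscale))
  invisible(x)
}

#' Log-density of the smoothing prior (up to a constant)
#'
#' `-1/2 s_E' C^{-1} s_E - 1/2 s_G' C^{-1} s_G` for the stacked state
#' `s = [s_E; s_G]` of log-variance values at the grid points.
#'
#' @param s Numeric vector of length `2 * length(prior$grid)`, residual block
#'   first.
#' @param prior A [gp_prior()] object.
#' @return Scalar log-density with normalizing constants dropped.
#' @export
log_prior <- function(s, prior) {
  N <- length(prior$grid)
  if (length(s) != 2 * N)
    stop("'s' must have length 2 * grid size (got ", length(s), ", expected ",
         2 * N, ")", call. = FALSE)
  sE <- s[seq_len(N)]
  sG <- s[N + seq_len(N)]
  -0.5 * sum(sE * (prior$C_inv %*% sE)) -
    0.5 * sum(sG * (prior$C_inv %*% sG))
}

# gradient of log_prior: -C^{-1} s blockwise
grad_log_prior <- function(s, prior) {
  N <- length(prior$grid)
  c(-prior$C_inv %*% s[seq_len(N)], -prior$C_inv %*% s[N + seq_len(N)])
}
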