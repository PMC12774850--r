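#' Assemble the phenotypic covariance matrix from the log-variance state
#'
#' The state holds the log variance curves at the grid points; the weight
#' matrix `W` carries them to the measurement points, where
#' `K = D_G G D_G + D_E^2` with `(D_G)_ii = sigma_G(t_i)` and
#' `(D_E)_ii = sigma_E(t_i)`.
#'
#' @param s State vector `[s_E; s_G]` of length `2 * ncol(W)`.
#' @param W Interpolation weight matrix (n x N), see [interp_weights()].
#' @param G n x n relationship matrix.
#' @return List with `K`, `sigma_g` (sd vector at measurement points),
#'   `sigma_e2` (residual variance vector).
#' @export
assemble_K <- function(s, W, G) {
  N <- ncol(W)
  if (length(s) != 2 * N)
    stop("'s' must have length 2 * ncol(W)", call. = FALSE)
  wsE <- drop(W %*% s[seq_len(N)])
  wsG <- drop(W %*% s[N + seq_len(N)])
  bad <- which(pmax(wsE, wsG) > 50)
  if (length(bad))
    stop("log-variance overflow at measurement index ", bad[1], call. = FALSE)
  sigma_g <- exp(0.5 * wsG)
  sigma_e2 <- exp(wsE)
  K <- tcrossprod(sigma_g) * G
  diag(K) <- diag(K) + sigma_e2
  list(K = K, sigma_g = sigma_g, sigma_e2 = sigma_e2)
}

#' Restricted log-likelihood of the data under covariance K
#'
#' Error-contrast (REML) log-likelihood
#' `-1/2 log|K| - 1/2 log|X'K^{-1}X| - 1/2 y'Py` with
#' `P = K^{-1} - K^{-1}X(X'K^{-1}X)^{-1}X'K^{-1}`; the additive constant is
#' fixed to zero. Free of the fixed effects: adding `X b` to `y` leaves the
#' value unchanged.
#'
#' @param data A [gprebe_data()] object.
#' @param K Positive-definite n x n covariance matrix.
#' @return Scalar restricted log-likelihood (constant dropped).
#' @export
restricted_loglik <- function(data, K) {
  ch <- tryCatch(chol(K), error = function(e)
    stop("'K' is not positive definite", call. = FALSE))
  Kinv <- chol2inv(ch)
  KX <- Kinv %*% data$X
  XtKX <- crossprod(data$X, KX)
  Py <- drop(Kinv %*% data$y - KX %*% solve(XtKX, crossprod(KX, data$y)))
  -sum(log(diag(ch))) - 0.5 * determinant(XtKX)$modulus[1] -
    0.5 * sum(data$y * Py)
}

# shared fast path: restricted log-likelihood (+ gradient, + AI) via compiled
# code; returns list(ok, loglik, grad?, ai?) or signals an error unless
# soft = TRUE (sampler path: non-finite states are rejected, not fatal)
eval_restricted <- function(s, data, prior, want_grad = FALSE,
                            want_ai = FALSE, soft = FALSE) {
  N <- length(prior$grid)
  out <- reml_eval_cpp(data$y, data$X, data$G, prior$W,
                       s[seq_len(N)], s[N + seq_len(N)],
                       want_grad, want_ai)
  if (!isTRUE(out$ok) && !soft)
    stop("restricted-likelihood evaluation failed (", out$reason, ")",
         call. = FALSE)
  out
}

#' Unnormalized log-posterior of the log-variance curves
#'
#' Restricted log-likelihood plus the Matern smoothing-prior log-density.
#'
#' @param s State vector `[s_E; s_G]`.
#' @param data A [gprebe_data()] object (phenotypes already on the scale the
#'   prior assumes; see [scale_data()]).
#' @param prior A [gp_prior()] object whose `W` maps grid to `data$t`.
#' @return Scalar unnormalized log-posterior.
#' @export
log_posterior <- function(s, data, prior) {
  eval_restricted(s, data, prior)$loglik + log_prior(s, prior)
}

#' Gradient of the log-posterior
#'
#' REML score adapted through the interpolation map, plus the prior gradient
#' `-C^{-1} s` blockwise. For grid coordinate j of either block the score is
#' `-1/2 tr(P dK/ds_j) + 1/2 y'P (dK/ds_j) P y`.
#'
#' @inheritParams log_posterior
#' @return Numeric vector of length `2N`, residual block first.
#' @export
grad_log_posterior <- function(s, data, prior) {
  drop(eval_restricted(s, data, prior, want_grad = TRUE)$grad) +
    grad_log_prior(s, prior)
}

#' Average-information matrix of the restricted likelihood
#'
#' `AI_{ij} = 1/2 y'P (dK/ds_i) P (dK/ds_j) P y`, the average of the observed
#' and expected information, returned in the positive (information)
#' convention so it is symmetric positive semidefinite.
#'
#' @inheritParams log_posterior
#' @return Symmetric PSD `2N x 2N` matrix.
#' @export
ai_matrix <- function(s, data, prior) {
  eval_restricted(s, data, prior, want_ai = TRUE)$ai
}

#' Bayesian average-information matrix
#'
#' Adds the prior precision `blockdiag(C^{-1}, C^{-1})` to the AI matrix,
#' giving the positive-definite curvature proxy used to precondition both the
#' Newton MAP search and the MALA proposals. If numerically non-PD, a ridge of
#' `1e-8 * trace / dim` is added, escalating tenfold.
#'
#' @param ai AI matrix from [ai_matrix()].
#' @param prior A [gp_prior()] object.
#' @return Symmetric positive-definite matrix with attribute `"chol"`.
#' @export
bai_matrix <- function(ai, prior) {
  N <- length(prior$grid)
  if (!all(dim(ai) == 2 * N))
    stop("'ai' must be 2N x 2N for the prior's grid size", call. = FALSE)
  B <- ai
  idx <- seq_len(N)
  B[idx, idx] <- B[idx, idx] + prior$C_inv
  B[N + idx, N + idx] <- B[N + idx, N + idx] + prior$C_inv
  B <- (B + t(B)) / 2
  ridge <- 1e-8 * sum(diag(B)) / (2 * N)
  added <- 0
  repeat {
    ch <- tryCatch(chol(B + diag(added, 2 * N)), error = function(e) NULL)
    if (!is.null(ch)) break
    added <- if (added == 0) ridge else added * 10
    if (added > 1e6 * ridge)
      stop("BAI matrix could not be made positive definite", call. = FALSE)
  }
  B <- B + diag(added, 2 * N)
  attr(B, "chol") <- ch
  B
}
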