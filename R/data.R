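#' Bundle phenotypes, covariate, fixed effects and relationship matrix
#'
#' Container for the data the dynamic mixed model operates on: one phenotype
#' and one covariate value per individual, an optional fixed-effect design
#' (default: an intercept column), and the additive relationship matrix G.
#'
#' @param y Phenotype vector (one measurement per individual).
#' @param t Covariate vector (time, age, temperature, ...), same length.
#' @param G n x n symmetric relationship matrix with positive diagonal.
#' @param X Optional n x p fixed-effect design of full column rank; defaults
#'   to a single column of ones.
#' @return Object of class `gprebe_data`.
#' @export
gprebe_data <- function(y, t, G, X = NULL) {
  y <- as.numeric(y); t <- as.numeric(t); G <- as.matrix(G)
  n <- length(y)
  if (length(t) != n) stop("'y' and 't' must have the same length",
                           call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(t)))
    stop("'y' and 't' must be finite with no missing values", call. = FALSE)
  if (nrow(G) != n || ncol(G) != n)
    stop("'G' must be ", n, " x ", n, " to match the phenotypes",
         call. = FALSE)
  if (any(!is.finite(G))) stop("'G' contains non-finite entries",
                               call. = FALSE)
  asym <- max(abs(G - t(G)))
  if (asym > 1e-8)
    stop("'G' is not symmetric (max |G_ij - G_ji| = ",
         format(asym, digits = 3), ")", call. = FALSE)
  if (any(diag(G) <= 0))
    stop("'G' must have strictly positive diagonal entries", call. = FALSE)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("'X' must have one row per individual",
                         call. = FALSE)
  if (qr(X)$rank < ncol(X) || ncol(X) >= n)
    stop("'X' must have full column rank with fewer columns than individuals",
         call. = FALSE)
  structure(list(y = y, t = t, X = X, G = (G + t(G)) / 2),
            class = "gprebe_data")
}

#' @export
print.gprebe_data <- function(x, ...) {
  cat(sprintf("gprebe_data: %d individuals, covariate range [%.4g, %.4g], %d fixed effect(s)\n",
              length(x$y), min(x$t), max(x$t), ncol(x$X)))
  invisible(x)
}

#' Scale phenotypes to sample variance 2
#'
#' The hyperparameter defaults assume phenotypes scaled so their sample
#' variance is exactly 2: at heritability 0.5 both variance components then
#' average one, i.e. zero on the log scale, matching the zero-mean GP prior.
#' Estimated variances are mapped back to original units by multiplying with
#' the squared factor.
#'
#' @param y Phenotype vector with positive sample variance.
#' @return List with `y` (scaled vector, sample variance 2) and `factor`
#'   (the divisor applied; variances back-transform via `factor^2`).
#' @export
scale_data <- function(y) {
  v <- stats::var(y)
  if (!is.finite(v) || v <= 0)
    stop("phenotype has zero variance; nothing to estimate", call. = FALSE)
  f <- sqrt(v / 2)
  list(y = y / f, factor = f)
}
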