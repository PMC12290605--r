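#' Matern 5/2 kernel
#'
#' \deqn{k(x, x') = \sigma^2 (1 + \sqrt{5} r + \tfrac{5}{3} r^2)
#'   e^{-\sqrt{5} r}, \quad r = |x - x'| / l,}
#' the covariance function of the latent Gaussian processes underlying the
#' Wishart process. The lengthscale \code{l} is in units of the normalized
#' \code{[0, 1]} scan-time index and controls how quickly the estimated
#' connectivity can change.
#'
#' @param x,x_prime numeric vectors of index locations.
#' @param variance kernel variance \eqn{\sigma^2 > 0}.
#' @param lengthscale kernel lengthscale \eqn{l > 0}.
#' @return the kernel matrix \code{length(x) x length(x_prime)} (a scalar
#'   for scalar inputs).
#' @examples
#' matern52(0, 1, variance = 1, lengthscale = 1)
#' @export
matern52 <- function(x, x_prime, variance = 1, lengthscale = 0.3) {
  stopifnot(variance > 0, lengthscale > 0)
  r <- abs(outer(x, x_prime, "-")) / lengthscale
  k <- variance * (1 + sqrt(5) * r + (5 / 3) * r^2) * exp(-sqrt(5) * r)
  if (length(x) == 1L && length(x_prime) == 1L) as.numeric(k) else k
}

#' Construct a covariance matrix from latent GP draws
#'
#' \deqn{\Sigma = A F F^T A^T + \mathrm{diag}(\Lambda)}
#' where \code{F} is the \code{D x nu} matrix of latent function values.
#' With \code{F} standard normal this is Wishart distributed with scale
#' matrix \code{A A^T} and \code{nu} degrees of freedom (plus the additive
#' diagonal noise).
#'
#' @param A \code{D x D} matrix (lower-triangular Cholesky factor of the
#'   scale matrix).
#' @param F_mat \code{D x nu} matrix of latent values.
#' @param Lambda vector of \code{D} non-negative noise variances.
#' @return symmetric \code{D x D} matrix.
#' @export
constructSigma <- function(A, F_mat, Lambda) {
  stopifnot(nrow(A) == ncol(A), nrow(F_mat) == nrow(A),
            all(Lambda >= 0))
  G <- A %*% F_mat
  S <- tcrossprod(G) + diag(rep_len(Lambda, nrow(A)), nrow(A))
  (S + t(S)) / 2
}

#' Wishart log-density
#'
#' Log of the Wishart density over positive definite matrices,
#' \deqn{f(\Sigma | V, \nu) = \frac{1}{Z} |\Sigma|^{(\nu - D - 1)/2}
#'   \exp(-\tfrac{1}{2} \mathrm{tr}(V^{-1} \Sigma)),}
#' with normalizer \eqn{Z = 2^{\nu D / 2} |V|^{\nu/2} \Gamma_D(\nu/2)}.
#' Used as an analytic oracle for the outer-product construction.
#'
#' @param Sigma positive definite \code{D x D} matrix.
#' @param V positive definite scale matrix.
#' @param nu degrees of freedom, \code{nu >= D} for a proper density.
#' @return log-density (numeric scalar).
#' @export
wishartLogPdf <- function(Sigma, V, nu) {
  Sigma <- as.matrix(Sigma); V <- as.matrix(V)
  D <- nrow(Sigma)
  stopifnot(nrow(V) == D, nu >= D)
  cS <- tryCatch(chol(Sigma), error = function(e) stop("Sigma not PD"))
  cV <- tryCatch(chol(V), error = function(e) stop("V not PD"))
  ldS <- 2 * sum(log(diag(cS)))
  ldV <- 2 * sum(log(diag(cV)))
  tr <- sum(diag(chol2inv(cV) %*% Sigma))
  lgammaD <- (D * (D - 1) / 4) * log(pi) +
    sum(lgamma(nu / 2 + (1 - seq_len(D)) / 2))
  logZ <- (nu * D / 2) * log(2) + (nu / 2) * ldV + lgammaD
  (nu - D - 1) / 2 * ldS - tr / 2 - logZ
}

#' Zero-mean Gaussian log-likelihood under the Wishart construction
#'
#' Evaluates \eqn{\log N(y; 0, \Sigma)} with
#' \eqn{\Sigma = A F F^T A^T + \mathrm{diag}(\Lambda)}, computed through a
#' Cholesky factorization (never an explicit inverse).
#'
#' @param y observation vector of length \code{D}.
#' @param A,F_mat,Lambda as in [constructSigma()].
#' @return log-likelihood (numeric scalar).
#' @export
conditionalLogLik <- function(y, A, F_mat, Lambda) {
  S <- constructSigma(A, F_mat, Lambda)
  gaussLogLik(y, S)
}

# zero-mean Gaussian log-density via Cholesky
gaussLogLik <- function(y, S) {
  D <- length(y)
  cS <- tryCatch(chol(S), error = function(e)
    stop("covariance numerically singular (rcond ~ ",
         format(rcond(S), digits = 3), ")"))
  z <- backsolve(cS, y, transpose = TRUE)
  -(D / 2) * log(2 * pi) - sum(log(diag(cS))) - sum(z^2) / 2
}

#' Convert a covariance matrix to a correlation matrix
#'
#' Divides each element by the product of the corresponding standard
#' deviations and forces an exact unit diagonal.
#'
#' @param Sigma covariance matrix with strictly positive diagonal.
#' @return correlation matrix.
#' @export
covToCor <- function(Sigma) {
  d <- diag(as.matrix(Sigma))
  if (any(d <= 0)) stop("covariance diagonal must be strictly positive")
  s <- 1 / sqrt(d)
  R <- Sigma * outer(s, s)
  diag(R) <- 1
  R
}

#' Project a symmetric matrix to the nearest correlation matrix
#'
#' Higham-style alternating projections between the PSD cone and the
#' unit-diagonal affine set. Used where pairwise-assembled estimates must
#' enter a Gaussian likelihood.
#'
#' @param R symmetric matrix with unit diagonal.
#' @param tol convergence tolerance on the change between iterates.
#' @param max_iter iteration cap.
#' @return the projected correlation matrix, with attribute
#'   \code{"changed"} (max absolute change from the input).
#' @export
nearestCorrelation <- function(R, tol = 1e-8, max_iter = 200) {
  X <- (R + t(R)) / 2
  dS <- matrix(0, nrow(R), ncol(R))
  Y <- X
  for (it in seq_len(max_iter)) {
    Rk <- Y - dS
    ev <- eigen(Rk, symmetric = TRUE)
    X <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
    dS <- X - Rk
    Y <- X
    diag(Y) <- 1
    if (max(abs(Y - X)) < tol &&
        min(eigen(Y, symmetric = TRUE, only.values = TRUE)$values) > -tol)
      break
  }
  out <- (Y + t(Y)) / 2
  diag(out) <- 1
  attr(out, "changed") <- max(abs(out - R))
  out
}
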