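# Shared oracles and small fixtures, independent of the package's own
# computation paths.

# dense zero-mean multivariate normal log-density via determinant/solve
# (deliberately not the Cholesky path used in the package)
mvnLogLikOracle <- function(y, S) {
  D <- length(y)
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  -0.5 * (D * log(2 * pi) + ld + drop(t(y) %*% solve(S) %*% y))
}

# brute-force elementwise RMSE between two D x D x N arrays
rmseOracle <- function(a, b, offdiag_only_pair = FALSE) {
  if (offdiag_only_pair) {
    d <- a[1, 2, ] - b[1, 2, ]
    return(sqrt(mean(d^2)))
  }
  tot <- 0; cnt <- 0
  for (n in seq_len(dim(a)[3]))
    for (i in seq_len(dim(a)[1]))
      for (j in seq_len(dim(a)[2])) {
        tot <- tot + (a[i, j, n] - b[i, j, n])^2
        cnt <- cnt + 1
      }
  sqrt(tot / cnt)
}

# log of the exact Gauss-Hermite-quadrature marginal likelihood of the
# D = 1, nu = 1 Wishart-process model: p(Y) = E_f[prod_n N(y_n; 0,
# a^2 f_n^2 + lambda)] with f ~ N(0, Kxx). Enumerates a tensor grid.
quadratureLogMarginal <- function(y, x, a, lambda, kvar, klen,
                                  n_nodes = 30) {
  gh <- pracma::gaussHermite(n_nodes)
  N <- length(y)
  K <- tvfc::matern52(x, x, variance = kvar, lengthscale = klen)
  L <- t(chol(K + diag(1e-10, N)))
  grids <- replicate(N, seq_len(n_nodes), simplify = FALSE)
  idx <- as.matrix(expand.grid(grids))
  logw <- log(gh$w) - log(sqrt(pi))
  total <- -Inf
  for (r in seq_len(nrow(idx))) {
    u <- sqrt(2) * gh$x[idx[r, ]]
    f <- as.numeric(L %*% u)
    s2 <- a^2 * f^2 + lambda
    ll <- sum(dnorm(y, 0, sqrt(s2), log = TRUE)) + sum(logw[idx[r, ]])
    total <- max(total, ll) + log1p(exp(min(total, ll) -
                                          max(total, ll)))
  }
  total
}
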