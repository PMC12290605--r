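#' PosteriorTVFC: posterior summaries of a Wishart-process fit
#'
#' @slot locations query times in \code{[0, 1]}.
#' @slot mean_corr \code{D x D x N} array of posterior mean correlations.
#' @slot lower,upper \code{D x D x N} arrays, mean -/+ 2 posterior SD.
#' @slot mean_cov \code{D x D x N} array of posterior mean covariances.
#' @slot n_samples number of Monte-Carlo posterior draws used.
#' @export
setClass("PosteriorTVFC",
  representation(locations = "numeric", mean_corr = "array",
                 lower = "array", upper = "array", mean_cov = "array",
                 n_samples = "integer"))

setMethod("show", "PosteriorTVFC", function(object) {
  d <- dim(object@mean_corr)
  cat(sprintf("PosteriorTVFC: D=%d, %d locations, %d posterior samples\n",
              d[1], d[3], object@n_samples))
})

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplusInv <- function(y) ifelse(y > 30, y, log(expm1(y)))
softplusGrad <- function(x) stats::plogis(x)

# ---- parameter packing ------------------------------------------------
# Unconstrained vector layout: A lower-tri (diag softplus), log-free
# lambda (softplus), kernel variance + lengthscale (softplus), whitened
# variational means, variational Cholesky factors (diag softplus).

wpParamSkeleton <- function(D, nu, M) {
  P <- D * nu
  list(D = D, nu = nu, M = M, P = P,
       n_A = D * (D + 1) / 2, n_C = M * (M + 1) / 2,
       ltA = which(lower.tri(diag(D), diag = TRUE)),
       ltC = which(lower.tri(diag(M), diag = TRUE)))
}

wpPack <- function(sk, A, lambda, kvar, klen, Vm, Vchol) {
  D <- sk$D; M <- sk$M; P <- sk$P
  rawA <- A
  diag(rawA) <- softplusInv(diag(A))
  rawC <- numeric(sk$n_C * P)
  for (j in seq_len(P)) {
    Cj <- Vchol[, , j]
    diag(Cj) <- softplusInv(diag(Cj))
    rawC[(j - 1) * sk$n_C + seq_len(sk$n_C)] <- Cj[sk$ltC]
  }
  c(rawA[sk$ltA], softplusInv(lambda), softplusInv(kvar),
    softplusInv(klen), as.numeric(Vm), rawC)
}

wpUnpack <- function(sk, theta) {
  D <- sk$D; M <- sk$M; P <- sk$P
  i <- 0L
  rawA <- matrix(0, D, D)
  rawA[sk$ltA] <- theta[i + seq_len(sk$n_A)]; i <- i + sk$n_A
  A <- rawA
  diag(A) <- softplus(diag(rawA))
  rawLam <- theta[i + seq_len(D)]; i <- i + D
  rawKv <- theta[i + 1L]; rawKl <- theta[i + 2L]; i <- i + 2L
  Vm <- matrix(theta[i + seq_len(M * P)], M, P); i <- i + M * P
  Vchol <- array(0, dim = c(M, M, P))
  rawCd <- vector("list", P)
  for (j in seq_len(P)) {
    Cj <- matrix(0, M, M)
    Cj[sk$ltC] <- theta[i + seq_len(sk$n_C)]; i <- i + sk$n_C
    rawCd[[j]] <- diag(Cj)
    diag(Cj) <- softplus(diag(Cj))
    Vchol[, , j] <- Cj
  }
  list(A = A, rawA = rawA, lambda = softplus(rawLam), rawLam = rawLam,
       kvar = softplus(rawKv), rawKv = rawKv,
       klen = softplus(rawKl), rawKl = rawKl,
       Vm = Vm, Vchol = Vchol, rawCd = rawCd)
}

# chain constrained-space gradients back to the unconstrained vector
wpPackGrad <- function(sk, par, res) {
  D <- sk$D; M <- sk$M; P <- sk$P
  gA <- res$gA
  diag(gA) <- diag(gA) * softplusGrad(diag(par$rawA))
  gLam <- res$glambda * softplusGrad(par$rawLam)
  gKv <- res$gkvar * softplusGrad(par$rawKv)
  gKl <- res$gklen * softplusGrad(par$rawKl)
  gC <- numeric(sk$n_C * P)
  for (j in seq_len(P)) {
    Gj <- res$gVchol[, , j]
    diag(Gj) <- diag(Gj) * softplusGrad(par$rawCd[[j]])
    gC[(j - 1) * sk$n_C + seq_len(sk$n_C)] <- Gj[sk$ltC]
  }
  c(gA[sk$ltA], gLam, gKv, gKl, as.numeric(res$gVmean), gC)
}

wpModelFromPar <- function(sk, par, Z, trace, config) {
  new("WPModel", D = as.integer(sk$D), nu = as.integer(sk$nu),
      M = as.integer(sk$M), A = par$A, Lambda = as.numeric(par$lambda),
      kernel = c(variance = par$kvar, lengthscale = par$klen),
      Z = Z, Vmean = par$Vm, Vchol = par$Vchol,
      trace = trace, config = config)
}

wpParFromModel <- function(model) {
  sk <- wpParamSkeleton(model@D, model@nu, model@M)
  theta <- wpPack(sk, model@A, model@Lambda,
                  model@kernel["variance"], model@kernel["lengthscale"],
                  model@Vmean, model@Vchol)
  wpUnpack(sk, theta)
}

#' Monte-Carlo estimate of the evidence lower bound
#'
#' Estimates the ELBO of a Wishart-process model: the Monte-Carlo
#' expectation of the conditional log-likelihood under the variational
#' posterior, minus the closed-form Gaussian KL divergence between the
#' whitened variational distributions and their standard-normal prior.
#'
#' @param model a [WPModel-class].
#' @param data a [TimeSeriesData-class].
#' @param n_mc number of Monte-Carlo samples (>= 1).
#' @param seed RNG seed for the reparameterized draws.
#' @return list with \code{elbo}, its Monte-Carlo standard error
#'   \code{se}, and the \code{data_term} and \code{kl} components.
#' @export
elboEstimate <- function(model, data, n_mc = 1000, seed = 1L) {
  stopifnot(is(model, "WPModel"), is(data, "TimeSeriesData"), n_mc >= 1)
  N <- nTimepoints(data)
  P <- model@D * model@nu
  set.seed(seed)
  eps <- array(rnorm(N * P * n_mc), dim = c(N, P, n_mc))
  res <- cpp_wp_elbo(observations(data), indexLocations(data), model@Z,
                     model@kernel["variance"], model@kernel["lengthscale"],
                     model@A, model@Lambda, model@Vmean, model@Vchol,
                     eps, 1e-6, FALSE, FALSE)
  se <- if (n_mc > 1) sd(res$elbo_samples) / sqrt(n_mc) else NA_real_
  list(elbo = res$elbo, se = se, data_term = res$data_term, kl = res$kl)
}

#' Fit a Wishart-process TVFC model
#'
#' Maximizes a reparameterized Monte-Carlo ELBO by Adam gradient ascent.
#' Trained parameters: the whitened variational means and Cholesky
#' factors of each latent GP, the shared Matern 5/2 kernel
#' hyperparameters, the lower-Cholesky scale factor \code{A}, and the
#' diagonal additive noise \code{Lambda}. Positivity is enforced through
#' softplus transforms. Defaults: \code{nu = D}, \code{M = min(200, N)},
#' learning rate 0.02, at most 5000 iterations, and one Monte-Carlo
#' sample per gradient step. Convergence is tracked on a fixed-draw
#' (common random numbers) ELBO monitor evaluated every 50 iterations;
#' training stops early once the monitor's relative improvement stays
#' below 1e-4 for \code{patience} consecutive evaluations. \code{A} is
#' initialized by moment matching to the sample covariance, the
#' variational distributions at the whitened prior.
#'
#' @param data a [TimeSeriesData-class] (columns should be z-scored).
#' @param nu degrees of freedom (default \code{D}).
#' @param M number of inducing points (default \code{min(200, N)}).
#' @param max_iter iteration cap for Adam.
#' @param lr Adam learning rate.
#' @param n_mc Monte-Carlo samples per gradient step.
#' @param seed RNG seed controlling the stochastic gradients.
#' @param patience number of consecutive stalled monitor evaluations
#'   (50 iterations apart) required to stop early.
#' @param init optional named list overriding initial values
#'   (\code{A}, \code{Lambda}, \code{kvar}, \code{klen}).
#' @param verbose print the ELBO every 200 iterations.
#' @return a fitted [WPModel-class]; the per-iteration Monte-Carlo ELBO
#'   trace is stored in slot \code{trace}.
#' @export
fitWishartProcess <- function(data, nu = NULL, M = NULL, max_iter = 5000,
                              lr = 0.02, n_mc = 1, seed = 1L,
                              patience = 6L, init = list(),
                              verbose = FALSE) {
  stopifnot(is(data, "TimeSeriesData"))
  Y <- observations(data)
  X <- indexLocations(data)
  N <- nrow(Y); D <- ncol(Y)
  stopifnot(N >= 4, D >= 2)
  if (is.null(nu)) nu <- D
  if (is.null(M)) M <- min(200L, N)
  nu <- as.integer(nu); M <- as.integer(M)
  stopifnot(nu >= D, M >= 2)
  P <- D * nu
  Z <- seq(0, 1, length.out = M)
  sk <- wpParamSkeleton(D, nu, M)

  # moment-matched initialization: with the variational posterior at the
  # whitened prior, E[Sigma] = nu * kvar * A A^T (+ Lambda), so starting
  # A at chol(S / (nu * kvar)) matches the sample covariance S
  A0 <- if (!is.null(init$A)) init$A else {
    S0 <- crossprod(sweep(Y, 2, colMeans(Y))) / (N - 1)
    kv0 <- if (!is.null(init$kvar)) init$kvar else 1
    t(chol(S0 / (nu * kv0) + diag(1e-8, D)))
  }
  lam0 <- rep_len(if (!is.null(init$Lambda)) init$Lambda else 0.01, D)
  kvar0 <- if (!is.null(init$kvar)) init$kvar else 1
  klen0 <- if (!is.null(init$klen)) init$klen else 0.3
  Vm0 <- matrix(0, M, P)
  Vc0 <- array(0, dim = c(M, M, P))
  for (j in seq_len(P)) Vc0[, , j] <- diag(M)

  theta <- wpPack(sk, A0, lam0, kvar0, klen0, Vm0, Vc0)
  mAdam <- numeric(length(theta))
  vAdam <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  trace <- numeric(0)
  set.seed(seed)
  # fixed-draw ELBO monitor: the stochastic per-step ELBO is too noisy
  # for a stopping rule, so convergence is tracked on a common-random-
  # numbers estimate that is deterministic given the parameters
  n_mon <- 8L
  eps_mon <- array(rnorm(N * P * n_mon), dim = c(N, P, n_mon))
  mon <- numeric(0)
  stall <- 0L
  last_par <- NULL
  for (it in seq_len(max_iter)) {
    par <- wpUnpack(sk, theta)
    eps <- array(rnorm(N * P * n_mc), dim = c(N, P, n_mc))
    res <- cpp_wp_elbo(Y, X, Z, par$kvar, par$klen, par$A, par$lambda,
                       par$Vm, par$Vchol, eps, 1e-6, TRUE, TRUE)
    if (!is.finite(res$elbo)) {
      warning("non-finite ELBO at iteration ", it,
              "; returning last finite state")
      par <- last_par
      break
    }
    last_par <- par
    trace <- c(trace, res$elbo)
    g <- wpPackGrad(sk, par, res)
    mAdam <- b1 * mAdam + (1 - b1) * g
    vAdam <- b2 * vAdam + (1 - b2) * g^2
    mhat <- mAdam / (1 - b1^it)
    vhat <- vAdam / (1 - b2^it)
    theta <- theta + lr * mhat / (sqrt(vhat) + adam_eps) # ascent
    if (verbose && it %% 200 == 0)
      message(sprintf("iter %d  elbo %.3f  (kl %.3f)", it, res$elbo,
                      res$kl))
    if (it %% 50 == 0) {
      mres <- cpp_wp_elbo(Y, X, Z, par$kvar, par$klen, par$A,
                          par$lambda, par$Vm, par$Vchol, eps_mon, 1e-6,
                          FALSE, FALSE)
      mon <- c(mon, mres$elbo)
      nm <- length(mon)
      if (nm >= 3) {
        rel <- (mon[nm] - mon[nm - 1]) / abs(mon[nm - 1])
        stall <- if (rel < 1e-4) stall + 1L else 0L
        if (stall >= patience) break
      }
    }
  }
  if (is.null(last_par)) stop("optimization failed at the first step")
  cfg <- list(nu = nu, M = M, max_iter = max_iter, lr = lr, n_mc = n_mc,
              seed = seed, N = N, D = D, iterations_run = length(trace))
  wpModelFromPar(sk, last_par, Z, trace, cfg)
}

#' Posterior time-varying correlation estimates
#'
#' Draws samples of the latent GPs at the query locations from the
#' variational posterior, maps each through the Wishart construction
#' \eqn{\Sigma = A F F^T A^T + \Lambda}, converts to correlations, and
#' summarizes elementwise as the posterior mean with a mean +/- 2 SD
#' band.
#'
#' @param model a fitted [WPModel-class].
#' @param locations query times in \code{[0, 1]}.
#' @param n_samples Monte-Carlo posterior draws (default 3000).
#' @param seed RNG seed.
#' @return a [PosteriorTVFC-class].
#' @export
posteriorTvfc <- function(model, locations, n_samples = 3000L,
                          seed = 1L) {
  stopifnot(is(model, "WPModel"), all(locations >= 0),
            all(locations <= 1), n_samples >= 2)
  pred <- cpp_wp_predictive(locations, model@Z, model@kernel["variance"],
                            model@kernel["lengthscale"], model@Vmean,
                            model@Vchol, 1e-6)
  set.seed(seed)
  post <- cpp_wp_posterior(pred$mu, pred$sdev, model@A, model@Lambda,
                           model@D, model@nu, as.integer(n_samples))
  new("PosteriorTVFC", locations = as.numeric(locations),
      mean_corr = post$mean_corr,
      lower = post$mean_corr - 2 * post$sd_corr,
      upper = post$mean_corr + 2 * post$sd_corr,
      mean_cov = post$mean_cov, n_samples = as.integer(n_samples))
}

#' Posterior-mean correlation trajectory of a Wishart-process fit
#'
#' @param model a fitted [WPModel-class].
#' @param locations query times (defaults to a regular grid of the
#'   training length stored in the model config).
#' @param n_samples posterior draws.
#' @param seed RNG seed.
#' @return a [CovTrajectory-class] of posterior-mean correlations.
#' @export
wpTvfc <- function(model, locations = NULL, n_samples = 3000L, seed = 1L) {
  if (is.null(locations)) locations <- normalizedLocations(model@config$N)
  post <- posteriorTvfc(model, locations, n_samples = n_samples,
                        seed = seed)
  newCovTrajectory(post@mean_corr, kind = "wp", validate = FALSE)
}
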