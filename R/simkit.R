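#' Synthetic covariance profiles
#'
#' Generates the time course sigma(n) of the off-diagonal covariance term
#' used by the simulation benchmarks. Seven deterministic structures are
#' available: a null (uncorrelated) profile, a constant profile, slow and
#' fast oscillating sines (one and three full periods over the scan),
#' a stepwise profile with two change points, a repeating state-transition
#' sequence, and a boxcar task design convolved with a canonical
#' hemodynamic response function.
#'
#' Default shape parameters: sine amplitude 0.8; stepwise levels
#' \code{0, 0.8, -0.6} over thirds of the scan; state-transition levels
#' \code{0.1, 0.5, -0.3, 0.7} repeating over 8 equal segments; boxcar
#' square wave of period \code{N/4} with levels \code{0, 0.8}, convolved
#' with a double-gamma HRF and renormalized to peak 0.8.
#'
#' @param kind one of \code{"null"}, \code{"constant"},
#'   \code{"periodic_slow"}, \code{"periodic_fast"}, \code{"stepwise"},
#'   \code{"state_transition"}, \code{"boxcar"}.
#' @param N number of time steps (>= 2).
#' @param constant value of the constant profile (default 0.8).
#' @param amplitude sine amplitude for the periodic profiles (default 0.8).
#' @param TR repetition time in seconds, used to sample the HRF for the
#'   boxcar profile (default 2).
#' @return numeric vector of length \code{N} with values in \code{[-1, 1]}.
#' @examples
#' p <- covarianceProfile("periodic_slow", 400)
#' range(p)
#' @export
covarianceProfile <- function(kind, N, constant = 0.8, amplitude = 0.8,
                              TR = 2) {
  if (length(kind) != 1L || !kind %in% PROFILE_KINDS)
    stop("unknown profile kind '", kind, "'; valid kinds: ",
         paste(PROFILE_KINDS, collapse = ", "))
  N <- as.integer(N)
  stopifnot(N >= 2)
  n <- seq_len(N) - 1L
  values <- switch(kind,
    null = rep(0, N),
    constant = rep(constant, N),
    periodic_slow = amplitude * sin(2 * pi * n / N),
    periodic_fast = amplitude * sin(2 * pi * 3 * n / N),
    stepwise = {
      v <- rep(0, N)
      v[n >= N / 3 & n < 2 * N / 3] <- 0.8
      v[n >= 2 * N / 3] <- -0.6
      v
    },
    state_transition = {
      levels <- c(0.1, 0.5, -0.3, 0.7)
      seg <- pmin(floor(n / (N / 8)), 7)
      levels[(seg %% 4) + 1]
    },
    boxcar = {
      square <- ifelse((n %% (N / 4)) < (N / 8), 0.8, 0)
      h <- hrfDoubleGamma(seq(0, 30, by = TR))
      v <- as.numeric(stats::convolve(square, rev(h), type = "open"))[seq_len(N)]
      v * 0.8 / max(abs(v))
    })
  stopifnot(all(values >= -1 - 1e-12), all(values <= 1 + 1e-12))
  values
}

#' Canonical double-gamma hemodynamic response function
#'
#' SPM-style difference of two gamma densities: response peak at 6 s,
#' undershoot peak at 16 s, undershoot ratio 1/6; normalized to peak 1.
#'
#' @param t time in seconds (vector).
#' @return numeric vector of HRF values.
#' @export
hrfDoubleGamma <- function(t) {
  stopifnot(all(t >= 0))
  peak <- stats::dgamma(t, shape = 6, rate = 1)
  under <- stats::dgamma(t, shape = 16, rate = 1)
  h <- peak - under / 6
  h / max(h)
}

#' Assemble a covariance trajectory from a profile
#'
#' Builds the sequence of \code{D x D} covariance matrices used to
#' generate synthetic data. With the bivariate topology the single
#' off-diagonal follows the profile directly. The dense topology places
#' the profile on every off-diagonal, first remapping its negative range
#' from \code{[-1, 0]} onto \code{[-0.5, 0]} so the equicorrelation
#' matrices stay positive semidefinite. The sparse topology correlates
#' only the first two nodes and leaves the rest independent.
#'
#' @param profile numeric vector (from [covarianceProfile()]).
#' @param D number of nodes (2 for bivariate, >= 3 for dense/sparse).
#' @param topology one of \code{"bivariate"}, \code{"dense"},
#'   \code{"sparse"}.
#' @param kind profile kind label stored on the result.
#' @return a [CovTrajectory-class] object.
#' @export
assembleTrajectory <- function(profile, D = 2,
                               topology = c("bivariate", "dense", "sparse"),
                               kind = "unknown") {
  topology <- match.arg(topology)
  N <- length(profile)
  D <- as.integer(D)
  if (topology == "bivariate" && D != 2L)
    stop("bivariate topology requires D = 2")
  if (topology != "bivariate" && D < 3L)
    stop("dense/sparse topologies require D >= 3")
  sig <- array(0, dim = c(D, D, N))
  for (n in seq_len(N)) sig[, , n] <- diag(D)
  if (topology == "bivariate") {
    sig[1, 2, ] <- sig[2, 1, ] <- profile
  } else if (topology == "sparse") {
    sig[1, 2, ] <- sig[2, 1, ] <- profile
  } else {
    dense <- ifelse(profile < 0, profile / 2, profile)
    # PSD bound for a D x D equicorrelation matrix is -1/(D-1)
    dense <- pmax(dense, -1 / (D - 1) + 1e-9)
    for (n in seq_len(N)) {
      m <- matrix(dense[n], D, D)
      diag(m) <- 1
      sig[, , n] <- m
    }
  }
  traj <- newCovTrajectory(sig, topology = topology, kind = kind,
                           validate = FALSE)
  ok <- validObject(traj, test = TRUE)
  if (!isTRUE(ok)) stop("assembled trajectory invalid: ", ok)
  traj
}

#' Sample a multivariate time series from a covariance trajectory
#'
#' Draws \code{y_n ~ N(0, Sigma_n)} independently across time steps, then
#' z-scores each column (mean 0, SD 1). Deterministic given \code{seed}.
#'
#' @param traj a [CovTrajectory-class].
#' @param seed integer RNG seed.
#' @param TR repetition time in seconds.
#' @param normalize z-score columns after sampling (default TRUE).
#' @return a [TimeSeriesData-class] object.
#' @export
sampleTimeSeries <- function(traj, seed = 1L, TR = 2, normalize = TRUE) {
  stopifnot(is(traj, "CovTrajectory"))
  N <- nTimepoints(traj)
  D <- nNodes(traj)
  set.seed(seed)
  Y <- matrix(NA_real_, N, D)
  for (n in seq_len(N)) {
    S <- traj@sigmas[, , n]
    ev <- eigen(S, symmetric = TRUE)
    if (min(ev$values) < -1e-10) stop("Sigma_", n, " is not PSD")
    R <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
    Y[n, ] <- R %*% rnorm(D)
  }
  if (normalize) Y <- scale(Y)[, , drop = FALSE]
  attr(Y, "scaled:center") <- NULL
  attr(Y, "scaled:scale") <- NULL
  newTimeSeriesData(Y, TR = TR, seed = seed)
}

#' Autocorrelated surrogate noise
#'
#' Generates \code{D} mutually independent AR(1) series with unit marginal
#' variance, mimicking the temporal autocorrelation of resting-state BOLD
#' noise. Column streams are independent, so cross-correlations are zero
#' in expectation.
#'
#' @param N,D dimensions of the noise matrix.
#' @param ar_coef AR(1) coefficient in \code{[0, 1)} (default 0.4).
#' @param seed integer RNG seed.
#' @return numeric \code{N x D} matrix.
#' @export
surrogateNoise <- function(N, D, ar_coef = 0.4, seed = 1L) {
  if (ar_coef < 0 || ar_coef >= 1)
    stop("ar_coef must lie in [0, 1) for stationarity")
  set.seed(seed)
  E <- matrix(NA_real_, N, D)
  for (d in seq_len(D)) {
    if (ar_coef == 0) {
      E[, d] <- rnorm(N)
    } else {
      E[, d] <- as.numeric(arima.sim(list(ar = ar_coef), n = N,
                                     sd = sqrt(1 - ar_coef^2)))
    }
  }
  E
}

#' Mix signal with noise at a given SNR
#'
#' Forms \code{Y* = alpha * Y + (1 - alpha) * E} with
#' \code{alpha = snr / (1 + snr)}, so that \code{snr = alpha / (1 - alpha)}.
#'
#' @param Y signal matrix.
#' @param E noise matrix, same shape as \code{Y}.
#' @param snr positive signal-to-noise ratio.
#' @return list with elements \code{Y} (mixed matrix) and \code{alpha}.
#' @export
mixNoise <- function(Y, E, snr) {
  if (!all(dim(Y) == dim(E))) stop("Y and E must have the same shape")
  stopifnot(snr > 0)
  alpha <- snr / (1 + snr)
  list(Y = alpha * Y + (1 - alpha) * E, alpha = alpha)
}

#' Adjust ground-truth correlations for added noise
#'
#' After mixing signal and independent noise, the observable correlation
#' shrinks. Assuming independence of signal and noise,
#' \deqn{\rho^*_{ij}(n) = \frac{\alpha^2 \sigma_{ij}(n)}
#'   {\sqrt{(\alpha^2 \sigma_{ii} + (1-\alpha)^2 v_i)
#'          (\alpha^2 \sigma_{jj} + (1-\alpha)^2 v_j)}}.}
#' Returned matrices are on the correlation scale (unit diagonal).
#'
#' @param traj ground-truth [CovTrajectory-class].
#' @param alpha mixing coefficient in \code{(0, 1)}.
#' @param noise_variances vector of noise variances (recycled to D;
#'   default 1).
#' @return a [CovTrajectory-class] on the correlation scale.
#' @export
adjustGroundTruth <- function(traj, alpha, noise_variances = 1) {
  stopifnot(is(traj, "CovTrajectory"), alpha > 0, alpha < 1,
            all(noise_variances > 0))
  D <- nNodes(traj)
  N <- nTimepoints(traj)
  v <- rep_len(noise_variances, D)
  out <- array(NA_real_, dim = c(D, D, N))
  for (n in seq_len(N)) {
    S <- traj@sigmas[, , n]
    tot <- alpha^2 * diag(S) + (1 - alpha)^2 * v
    scale <- sqrt(outer(tot, tot))
    m <- alpha^2 * S / scale
    diag(m) <- 1
    out[, , n] <- m
  }
  newCovTrajectory(out, topology = traj@topology, kind = traj@kind,
                   validate = FALSE)
}

#' Generate a complete synthetic benchmark dataset
#'
#' Convenience wrapper: builds the profile, assembles the trajectory,
#' samples observations, optionally mixes in AR(1) surrogate noise at a
#' given SNR and adjusts the ground truth accordingly.
#'
#' @param kind profile kind (see [covarianceProfile()]).
#' @param N number of time steps (default 400).
#' @param D number of nodes (default 2).
#' @param topology trajectory topology (default bivariate for D = 2).
#' @param snr signal-to-noise ratio, or \code{NULL} for noiseless data.
#' @param ar_coef AR(1) coefficient of the surrogate noise.
#' @param TR repetition time in seconds.
#' @param seed integer RNG seed.
#' @return list with \code{data} ([TimeSeriesData-class]) and \code{truth}
#'   (correlation-scale [CovTrajectory-class], noise-adjusted if
#'   \code{snr} is given).
#' @export
simulateDataset <- function(kind, N = 400, D = 2,
                            topology = if (D == 2) "bivariate" else "sparse",
                            snr = NULL, ar_coef = 0.4, TR = 2, seed = 1L) {
  prof <- covarianceProfile(kind, N, TR = TR)
  traj <- assembleTrajectory(prof, D = D, topology = topology, kind = kind)
  data <- sampleTimeSeries(traj, seed = seed, TR = TR)
  if (is.null(snr)) return(list(data = data, truth = traj))
  E <- surrogateNoise(N, D, ar_coef = ar_coef, seed = seed + 1000003L)
  mixed <- mixNoise(observations(data), E, snr)
  truth <- adjustGroundTruth(traj, mixed$alpha, noise_variances = 1)
  Ystar <- scale(mixed$Y)
  attr(Ystar, "scaled:center") <- NULL
  attr(Ystar, "scaled:scale") <- NULL
  list(data = newTimeSeriesData(Ystar, TR = TR, seed = seed), truth = truth)
}
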