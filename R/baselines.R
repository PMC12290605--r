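#' Static functional connectivity
#'
#' The unbiased covariance estimator
#' \eqn{\hat\Sigma = \frac{1}{N-1} \sum_n y_n y_n^T} (columns demeaned
#' first, matching the zero-mean convention), plus its Pearson
#' correlation matrix.
#'
#' @param Y numeric \code{N x D} matrix, or a [TimeSeriesData-class].
#' @return list with \code{cov} and \code{cor} matrices.
#' @export
staticFC <- function(Y) {
  if (is(Y, "TimeSeriesData")) Y <- observations(Y)
  Y <- as.matrix(Y)
  N <- nrow(Y)
  stopifnot(N >= 2)
  Yc <- sweep(Y, 2, colMeans(Y))
  S <- crossprod(Yc) / (N - 1)
  sds <- sqrt(diag(S))
  if (any(sds == 0))
    stop("constant column(s) ", paste(which(sds == 0), collapse = ", "),
         ": correlation undefined")
  list(cov = S, cor = covToCor(S))
}

#' Static-FC correlation trajectory
#'
#' The static estimate replicated at every time step, for comparison
#' with time-varying estimators.
#'
#' @param data a [TimeSeriesData-class] or matrix.
#' @return a [CovTrajectory-class].
#' @export
sfcTvfc <- function(data) {
  Y <- if (is(data, "TimeSeriesData")) observations(data) else as.matrix(data)
  R <- staticFC(Y)$cor
  sig <- array(R, dim = c(ncol(Y), ncol(Y), nrow(Y)))
  newCovTrajectory(sig, kind = "sfc", validate = FALSE)
}

#' Zero-phase Butterworth high-pass filter
#'
#' 5th-order Butterworth high-pass applied forward and backward
#' (zero phase) to each column.
#'
#' @param Y numeric matrix (columns filtered independently).
#' @param cutoff_hz cutoff frequency in Hz, below the Nyquist frequency
#'   \code{1 / (2 TR)}.
#' @param TR repetition time in seconds.
#' @param order filter order (default 5).
#' @return filtered matrix of the same shape.
#' @export
highpassFilter <- function(Y, cutoff_hz, TR, order = 5) {
  Y <- as.matrix(Y)
  nyq <- 1 / (2 * TR)
  if (cutoff_hz >= nyq)
    stop("cutoff ", cutoff_hz, " Hz is at or above Nyquist ", nyq, " Hz")
  if (cutoff_hz <= 0) return(Y)
  bf <- signal::butter(order, cutoff_hz / nyq, type = "high")
  N <- nrow(Y)
  # reflect the series at both ends before the forward-backward pass to
  # suppress edge transients, then trim back to length N
  npad <- min(N - 1, max(3 * order, ceiling(12 / (cutoff_hz * TR))))
  apply(Y, 2, function(col) {
    ext <- c(2 * col[1] - col[npad:2 + 1], col,
             2 * col[N] - col[(N - 1):(N - npad)])
    signal::filtfilt(bf, ext)[(npad + 1):(npad + N)]
  })
}

windowVolumes <- function(omega_s, TR) {
  w <- round(omega_s / TR)
  if (w < 2) stop("window of ", omega_s, " s is shorter than 2 volumes")
  as.integer(w)
}

# windowed raw second-moment sums via cumulative sums; Ypad is the
# (already zero-padded) matrix, w the window in volumes
runningCrossprod <- function(Ypad, w) {
  D <- ncol(Ypad)
  idx <- utils::combn(D, 2, simplify = FALSE)
  prods <- cbind(Ypad^2,
                 sapply(idx, function(ij) Ypad[, ij[1]] * Ypad[, ij[2]]))
  cs <- apply(prods, 2, cumsum)
  cs <- rbind(0, cs)
  list(sums = cs[(w + 1):nrow(cs), , drop = FALSE] -
         cs[1:(nrow(cs) - w), , drop = FALSE], pairs = idx)
}

#' Sliding-window TVFC estimation
#'
#' High-pass filters the series at \code{1 / omega} Hz, zero-pads
#' \code{floor(w/2)} volumes at each end, and slides a rectangular
#' window of length \code{omega} seconds in steps of one volume,
#' computing the correlation of the raw (zero-mean convention) second
#' moments within each window. Returns one correlation matrix per
#' original time step.
#'
#' @param data a [TimeSeriesData-class] or matrix (assumed z-scored).
#' @param omega window length in seconds.
#' @param TR repetition time (taken from \code{data} when available).
#' @param filter apply the high-pass filter (default TRUE).
#' @return a [CovTrajectory-class] of correlation matrices.
#' @export
slidingWindowTvfc <- function(data, omega, TR = NULL, filter = TRUE) {
  if (is(data, "TimeSeriesData")) {
    if (is.null(TR)) TR <- repetitionTime(data)
    Y <- observations(data)
  } else {
    if (is.null(TR)) stop("TR must be supplied for matrix input")
    Y <- as.matrix(data)
  }
  N <- nrow(Y); D <- ncol(Y)
  w <- windowVolumes(omega, TR)
  if (filter && (1 / omega) < 1 / (2 * TR))
    Y <- highpassFilter(Y, 1 / omega, TR)
  pad <- floor(w / 2)
  Ypad <- rbind(matrix(0, pad, D), Y, matrix(0, pad, D))
  rc <- runningCrossprod(Ypad, w)
  # window starting at row s of Ypad covers original index s - pad ... ;
  # center estimate n uses rows n .. n + w - 1 of Ypad
  sums <- rc$sums[seq_len(N), , drop = FALSE]
  sig <- array(NA_real_, dim = c(D, D, N))
  vars <- sums[, seq_len(D), drop = FALSE]
  vars[vars <= 0] <- NA_real_
  for (n in seq_len(N)) {
    m <- diag(D)
    for (p in seq_along(rc$pairs)) {
      ij <- rc$pairs[[p]]
      r <- sums[n, D + p] / sqrt(vars[n, ij[1]] * vars[n, ij[2]])
      m[ij[1], ij[2]] <- m[ij[2], ij[1]] <- max(-1, min(1, r))
    }
    sig[, , n] <- m
  }
  newCovTrajectory(sig, kind = "sw", validate = FALSE)
}

#' Cross-validated window length selection
#'
#' For every candidate window length, each evaluation point is scored by
#' the zero-mean Gaussian log-likelihood of the held-out observation
#' under the covariance estimated from its surrounding window (the
#' evaluation point itself excluded). The window maximizing the mean
#' log-likelihood is selected; ties go to the shortest window.
#' Evaluation points are all volumes for which the largest candidate
#' window fits entirely inside the scan. Scoring uses the unfiltered
#' series so that candidate likelihoods are comparable: the
#' window-dependent high-pass filter would shrink the variance of the
#' held-out observations by a different amount per candidate, distorting
#' the selection. The \code{1 / omega} filter is applied in the final
#' sliding-window estimation instead.
#'
#' @param data a [TimeSeriesData-class].
#' @param grid candidate window lengths in seconds (default
#'   \code{seq(omega_min, omega_max, by = 2 * TR)}).
#' @param omega_min,omega_max window-length bounds in seconds
#'   (defaults 20 and 180).
#' @return list with \code{omega} (selected length, seconds),
#'   \code{scores} (data.frame of \code{omega}, \code{mean_loglik}) and
#'   \code{n_eval}.
#' @export
cvWindowLength <- function(data, grid = NULL, omega_min = 20,
                           omega_max = 180) {
  stopifnot(is(data, "TimeSeriesData"))
  TR <- repetitionTime(data)
  if (is.null(grid)) grid <- seq(omega_min, omega_max, by = 2 * TR)
  stopifnot(all(grid >= omega_min - 1e-9), all(grid <= omega_max + 1e-9))
  Yall <- observations(data)
  N <- nrow(Yall); D <- ncol(Yall)
  wmax <- windowVolumes(max(grid), TR)
  half_max <- floor(wmax / 2)
  evals <- seq.int(half_max + 1L, N - half_max)
  if (length(evals) <= 0) stop("series too short for the window grid")
  scores <- numeric(length(grid))
  c0 <- -(D / 2) * log(2 * pi)
  Y <- Yall
  for (gi in seq_along(grid)) {
    omega <- grid[gi]
    w <- windowVolumes(omega, TR)
    half <- floor(w / 2)
    # raw second-moment sums over centered windows, eval point excluded
    prods <- array(NA_real_, dim = c(N, D, D))
    for (i in seq_len(D)) for (j in i:D)
      prods[, i, j] <- prods[, j, i] <- Y[, i] * Y[, j]
    cs <- apply(prods, c(2, 3), cumsum)
    cs <- array(rbind(matrix(0, 1, D * D), matrix(cs, N, D * D)),
                dim = c(N + 1, D, D))
    ll <- numeric(length(evals))
    for (ei in seq_along(evals)) {
      n <- evals[ei]
      lo <- max(1L, n - half); hi <- min(N, n + half)
      Ssum <- cs[hi + 1, , ] - cs[lo, , ] - prods[n, , ]
      Shat <- Ssum / (hi - lo - 1L) # count excluding eval point, minus 1
      Shat <- matrix(Shat, D, D)
      cS <- tryCatch(chol(Shat), error = function(e) NULL)
      if (is.null(cS)) { ll[ei] <- -Inf; next }
      zq <- backsolve(cS, Y[n, ], transpose = TRUE)
      ll[ei] <- c0 - sum(log(diag(cS))) - sum(zq^2) / 2
    }
    scores[gi] <- mean(ll)
  }
  best <- which(scores >= max(scores) - 1e-9)[1] # smallest omega wins ties
  list(omega = grid[best],
       scores = data.frame(omega = grid, mean_loglik = scores),
       n_eval = length(evals))
}

#' Sliding-window TVFC with cross-validated window length
#'
#' @inheritParams cvWindowLength
#' @return a [CovTrajectory-class]; the selected window length (seconds)
#'   is stored in attribute \code{"omega"} and the per-candidate score
#'   table in attribute \code{"window_scores"}.
#' @export
swCvTvfc <- function(data, grid = NULL, omega_min = 20, omega_max = 180,
                     filter = TRUE) {
  cv <- cvWindowLength(data, grid = grid, omega_min = omega_min,
                       omega_max = omega_max)
  traj <- slidingWindowTvfc(data, cv$omega, filter = filter)
  traj@kind <- "sw_cv"
  attr(traj, "omega") <- cv$omega
  attr(traj, "window_scores") <- cv$scores
  traj
}

#' Fit a GARCH(1,1) model by Gaussian quasi-maximum likelihood
#'
#' Conditional variance recursion
#' \eqn{h_n = \omega_0 + a y_{n-1}^2 + b h_{n-1}} with covariance
#' stationarity \eqn{a + b < 1} enforced through a simplex
#' reparameterization. Returns the parameter estimates and the
#' standardized residuals \eqn{z_n = y_n / \sqrt{h_n}}.
#'
#' @param y numeric vector (zero-mean series).
#' @return list with \code{omega0}, \code{a_arch}, \code{b_garch},
#'   \code{uncond_var}, \code{residuals}, \code{h}, \code{loglik} and
#'   logical \code{at_boundary} (stationarity boundary flag).
#' @export
garchFit11 <- function(y) {
  y <- as.numeric(y)
  N <- length(y)
  stopifnot(N >= 20)
  v <- var(y)
  if (v < .Machine$double.eps)
    stop("constant series: variance process degenerate")
  # (p1, p2, p3) -> omega0 = exp(p1), (a, b) = simplex(p2, p3) * 0.999
  toPar <- function(p) {
    e2 <- exp(p[2]); e3 <- exp(p[3])
    s <- 1 + e2 + e3
    c(omega0 = exp(p[1]), a = 0.999 * e2 / s, b = 0.999 * e3 / s)
  }
  nll <- function(p) {
    q <- toPar(p)
    r <- cpp_garch11_nll(y, q[1], q[2], q[3], v)
    if (!is.finite(r$nll)) 1e10 else r$nll
  }
  p0 <- c(log(v * 0.1), log(0.05 / 0.85), 0)
  opt <- optim(p0, nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  q <- toPar(opt$par)
  r <- cpp_garch11_nll(y, q[1], q[2], q[3], v)
  h <- as.numeric(r$h)
  list(omega0 = unname(q[1]), a_arch = unname(q[2]),
       b_garch = unname(q[3]),
       uncond_var = unname(q[1] / (1 - q[2] - q[3])),
       residuals = y / sqrt(h), h = h, loglik = -r$nll,
       at_boundary = (q[2] + q[3]) > 0.995)
}

#' DCC(1,1) correlation recursion
#'
#' \deqn{Q_n = (1 - a - b)\bar{Q} + a z_{n-1} z_{n-1}^T + b Q_{n-1},
#'   \quad Q_1 = \bar{Q},}
#' normalized to correlations
#' \eqn{R_n = \mathrm{diag}(Q_n)^{-1/2} Q_n \mathrm{diag}(Q_n)^{-1/2}}.
#'
#' @param Z \code{N x D} matrix of standardized residuals.
#' @param Qbar unconditional correlation target.
#' @param a,b DCC parameters, \code{a, b >= 0}, \code{a + b < 1}.
#' @return \code{D x D x N} array of correlation matrices.
#' @export
dccRecursion <- function(Z, Qbar, a, b) {
  stopifnot(a >= 0, b >= 0, a + b < 1)
  cpp_dcc_filter(as.matrix(Z), as.matrix(Qbar), a, b, TRUE)$R
}

dccStage2 <- function(Z) {
  Qbar <- cor(Z) # correlation targeting
  nll <- function(p) {
    e1 <- exp(p[1]); e2 <- exp(p[2])
    s <- 1 + e1 + e2
    a <- 0.999 * e1 / s; b <- 0.999 * e2 / s
    r <- cpp_dcc_filter(Z, Qbar, a, b, FALSE)$nll
    if (!is.finite(r)) 1e10 else r
  }
  opt <- optim(c(log(0.05 / 0.9), log(0.85 / 0.1)), nll,
               method = "Nelder-Mead",
               control = list(maxit = 1000, reltol = 1e-9))
  e1 <- exp(opt$par[1]); e2 <- exp(opt$par[2])
  s <- 1 + e1 + e2
  list(a = 0.999 * e1 / s, b = 0.999 * e2 / s, Qbar = Qbar)
}

#' DCC(1,1)-GARCH(1,1) TVFC estimation
#'
#' Two-stage quasi-maximum likelihood: univariate GARCH(1,1) per node,
#' then a DCC(1,1) recursion on the standardized residuals with
#' correlation targeting. In \code{"joint"} mode one DCC model covers
#' all \code{D} series; in \code{"bivariate_loop"} mode \code{D(D-1)/2}
#' pairwise models are fitted and assembled edgewise (which can break
#' positive semidefiniteness; non-PSD time steps are counted in
#' attribute \code{"n_nonpsd"} and consumers needing a likelihood should
#' project via [nearestCorrelation()]).
#'
#' @param data a [TimeSeriesData-class] or matrix.
#' @param mode \code{"joint"} or \code{"bivariate_loop"}.
#' @return a [CovTrajectory-class] of correlation matrices, with
#'   attributes \code{"params"} (list of GARCH and DCC estimates) and
#'   \code{"n_nonpsd"}.
#' @export
dccTvfc <- function(data, mode = c("joint", "bivariate_loop")) {
  mode <- match.arg(mode)
  Y <- if (is(data, "TimeSeriesData")) observations(data) else as.matrix(data)
  N <- nrow(Y); D <- ncol(Y)
  stopifnot(D >= 2)
  gfits <- lapply(seq_len(D), function(d) garchFit11(Y[, d]))
  Z <- sapply(gfits, `[[`, "residuals")
  n_nonpsd <- 0L
  if (mode == "joint" || D == 2) {
    st2 <- dccStage2(Z)
    R <- dccRecursion(Z, st2$Qbar, st2$a, st2$b)
    params <- list(garch = gfits, dcc = st2)
  } else {
    R <- array(0, dim = c(D, D, N))
    for (n in seq_len(N)) R[, , n] <- diag(D)
    params <- list(garch = gfits, dcc = list())
    for (i in seq_len(D - 1)) for (j in (i + 1):D) {
      st2 <- dccStage2(Z[, c(i, j)])
      Rp <- dccRecursion(Z[, c(i, j)], st2$Qbar, st2$a, st2$b)
      R[i, j, ] <- R[j, i, ] <- Rp[1, 2, ]
      params$dcc[[paste(i, j, sep = "-")]] <- st2
    }
    for (n in seq_len(N)) {
      ev <- min(eigen(R[, , n], symmetric = TRUE, only.values = TRUE)$values)
      if (ev < -1e-10) n_nonpsd <- n_nonpsd + 1L
    }
    if (n_nonpsd > 0)
      message("dccTvfc: ", n_nonpsd, "/", N,
              " pairwise-assembled matrices are non-PSD (raw values kept)")
  }
  traj <- newCovTrajectory(R, kind = if (mode == "joint") "dcc_joint"
                                     else "dcc_bl", validate = FALSE)
  attr(traj, "params") <- params
  attr(traj, "n_nonpsd") <- n_nonpsd
  traj
}
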