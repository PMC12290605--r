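#' Gaussian similarity kernel between subjects
#'
#' \eqn{K_a[s, s'] = \exp(-\lVert x_s - x_{s'} \rVert^2)} on
#' column-standardized feature vectors (one row per subject, features
#' are typically the lower-triangular edge values of a TVFC summary
#' measure). Zero-variance columns are dropped with a warning. With an
#' optional median heuristic the squared distances are divided by their
#' median before exponentiation.
#'
#' @param features \code{S x P} numeric matrix.
#' @param standardize z-score columns first (default TRUE).
#' @param median_heuristic scale distances by their median (default
#'   FALSE; the plain kernel has unit bandwidth).
#' @return symmetric \code{S x S} matrix with unit diagonal.
#' @export
similarityKernel <- function(features, standardize = TRUE,
                             median_heuristic = FALSE) {
  X <- as.matrix(features)
  stopifnot(nrow(X) >= 2)
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " zero-variance feature column(s)")
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (standardize) X <- scale(X)
  sq <- as.matrix(dist(X))^2
  if (median_heuristic) {
    med <- stats::median(sq[upper.tri(sq)])
    if (med > 0) sq <- sq / med
  }
  K <- exp(-sq)
  diag(K) <- 1
  dimnames(K) <- NULL
  K
}

#' Morphometricity: variance explained by a similarity kernel
#'
#' Restricted maximum likelihood fit of the linear mixed model
#' \eqn{y = X\beta + a + \epsilon} with \eqn{a \sim N(0, \sigma_a^2 K_a)}
#' and \eqn{\epsilon \sim N(0, \sigma_e^2 I)}. The restricted likelihood
#' is profiled down to the scalar variance ratio
#' \eqn{\gamma = \sigma_a^2 / \sigma_e^2} (optimized on a log grid via
#' [stats::optimize()]), after rotating into the eigenbasis of
#' \eqn{K_a}. Morphometricity is
#' \eqn{m^2 = \sigma_a^2 / (\sigma_a^2 + \sigma_e^2)}, clipped to
#' \code{[0, 1]}.
#'
#' @param y numeric phenotype vector (length S).
#' @param X design matrix of nuisance covariates (default: intercept
#'   only).
#' @param Ka \code{S x S} positive semidefinite similarity kernel.
#' @return list with \code{m2}, \code{sigma_a2}, \code{sigma_e2},
#'   \code{beta}, \code{loglik} (restricted), and \code{converged}.
#' @export
morphometricity <- function(y, X = NULL, Ka) {
  y <- as.numeric(y)
  S <- length(y)
  if (is.null(X)) X <- matrix(1, S, 1)
  X <- as.matrix(X)
  C <- ncol(X)
  stopifnot(nrow(Ka) == S, ncol(Ka) == S, S > C + 2)
  eg <- eigen((Ka + t(Ka)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yr <- crossprod(U, y)
  Xr <- crossprod(U, X)
  # restricted log-likelihood profiled over sigma_e^2, as a function of
  # log(gamma); V = sigma_e^2 (gamma * Ka + I)
  restLL <- function(lg) {
    g <- exp(lg)
    w <- g * d + 1
    XtVX <- crossprod(Xr, Xr / w)
    cX <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(cX)) return(-1e10)
    beta <- backsolve(cX, backsolve(cX, crossprod(Xr, yr / w),
                                    transpose = TRUE))
    r <- yr - Xr %*% beta
    quad <- sum(r^2 / w)
    se2 <- quad / (S - C)
    -0.5 * (sum(log(w)) + 2 * sum(log(diag(cX))) +
            (S - C) * log(se2) + (S - C))
  }
  opt <- optimize(restLL, interval = c(-12, 12), maximum = TRUE,
                  tol = 1e-8)
  g <- exp(opt$maximum)
  w <- g * d + 1
  XtVX <- crossprod(Xr, Xr / w)
  beta <- solve(XtVX, crossprod(Xr, yr / w))
  r <- yr - Xr %*% beta
  se2 <- sum(r^2 / w) / (S - C)
  sa2 <- g * se2
  m2 <- min(1, max(0, sa2 / (sa2 + se2)))
  conv <- abs(opt$maximum) < 12 - 1e-3 # interior optimum
  list(m2 = m2, sigma_a2 = sa2, sigma_e2 = se2,
       beta = as.numeric(beta), loglik = opt$objective,
       converged = conv)
}

#' Edgewise intraclass correlation coefficients
#'
#' One-way random-effects ANOVA (ICC(1,1) convention) per edge:
#' \eqn{\mathrm{ICC} = \sigma_X^2 / (\sigma_X^2 + \sigma_U^2)} with
#' \eqn{\sigma_X^2} the between-subject and \eqn{\sigma_U^2} the
#' within-subject variance, clipped to \code{[0, 1]}.
#'
#' @param measure subjects x sessions matrix for one edge, or a
#'   3-d array subjects x sessions x edges.
#' @return for a matrix, a list with \code{icc}, \code{sigma_X2},
#'   \code{sigma_U2}; for an array, a data.frame with one row per edge.
#' @export
iccEdgewise <- function(measure) {
  if (length(dim(measure)) == 3L) {
    E <- dim(measure)[3]
    return(do.call(rbind, lapply(seq_len(E), function(e) {
      r <- iccEdgewise(measure[, , e])
      data.frame(edge = e, icc = r$icc, sigma_X2 = r$sigma_X2,
                 sigma_U2 = r$sigma_U2)
    })))
  }
  m <- as.matrix(measure)
  S <- nrow(m); k <- ncol(m)
  stopifnot(S >= 3, k >= 2)
  if (all(m == m[1, 1])) {
    warning("degenerate (constant) measure; ICC defined as 0")
    return(list(icc = 0, sigma_X2 = 0, sigma_U2 = 0))
  }
  subj_means <- rowMeans(m)
  grand <- mean(m)
  msb <- k * sum((subj_means - grand)^2) / (S - 1)
  msw <- sum((m - subj_means)^2) / (S * (k - 1))
  sigma_X2 <- max(0, (msb - msw) / k)
  sigma_U2 <- msw
  icc <- if (sigma_X2 + sigma_U2 == 0) 0 else
    min(1, max(0, sigma_X2 / (sigma_X2 + sigma_U2)))
  list(icc = icc, sigma_X2 = sigma_X2, sigma_U2 = sigma_U2)
}

#' Image intraclass correlation coefficient (I2C2)
#'
#' Whole-image test-retest reliability,
#' \eqn{\mathrm{I2C2} = \mathrm{tr}(K_X) / \mathrm{tr}(K_X + K_U)},
#' with the between-subject (\eqn{K_X}) and within-subject error
#' (\eqn{K_U}) covariances of the edge vectors estimated by the method
#' of moments over session replicates; negative trace contributions are
#' clipped at zero.
#'
#' @param features array subjects x sessions x edges.
#' @return numeric scalar in \code{[0, 1]}.
#' @export
i2c2 <- function(features) {
  stopifnot(length(dim(features)) == 3L)
  S <- dim(features)[1]; k <- dim(features)[2]
  stopifnot(S >= 3, k >= 2)
  subj_mean <- apply(features, c(1, 3), mean) # S x E
  # within-subject error covariance trace
  dev_w <- sweep(features, c(1, 3), subj_mean)
  tr_KU <- sum(dev_w^2) / (S * (k - 1))
  # between: covariance of subject means contains KX + KU / k
  dev_b <- sweep(subj_mean, 2, colMeans(subj_mean))
  tr_means <- sum(dev_b^2) / (S - 1)
  tr_KX <- max(0, tr_means - tr_KU / k)
  if (tr_KX + tr_KU == 0) {
    warning("degenerate features; I2C2 defined as 0")
    return(0)
  }
  min(1, max(0, tr_KX / (tr_KX + tr_KU)))
}

#' Brain states by k-means clustering of correlation matrices
#'
#' Pools the vectorized lower-triangular correlations of all scans,
#' extracts \code{k} centroid matrices ("brain states") with k-means
#' (10 restarts, seeded), and labels every time step of every scan.
#' A switch is a change of assigned state between consecutive volumes.
#'
#' @param trajs list of [CovTrajectory-class] objects (one per scan).
#' @param k number of states (default 3).
#' @param seed RNG seed for the k-means restarts.
#' @return list with \code{states} (list of D x D centroid correlation
#'   matrices), \code{labels} (list of per-scan label vectors),
#'   \code{switches} (integer vector of per-scan switch counts).
#' @export
brainStates <- function(trajs, k = 3, seed = 1L) {
  if (is(trajs, "CovTrajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1, k >= 1)
  D <- nNodes(trajs[[1]])
  lt <- which(lower.tri(diag(D)))
  vecs <- lapply(trajs, function(tr)
    matrix(apply(tr@sigmas, 3, function(m) m[lt]),
           ncol = length(lt), byrow = TRUE))
  pooled <- do.call(rbind, vecs)
  if (ncol(pooled) == 0 || nrow(pooled) < k)
    stop("need at least k pooled time points")
  set.seed(seed)
  km <- NULL
  for (attempt in seq_len(10)) {
    km <- tryCatch(kmeans(pooled, centers = k, nstart = 10,
                          iter.max = 100),
                   error = function(e) NULL)
    if (!is.null(km)) break
  }
  if (is.null(km)) stop("k-means failed after 10 restarts")
  lengths <- vapply(vecs, nrow, 1L)
  ends <- cumsum(lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  labels <- lapply(seq_along(vecs), function(s)
    km$cluster[starts[s]:ends[s]])
  states <- lapply(seq_len(k), function(ki) {
    m <- diag(D)
    m[lt] <- km$centers[ki, ]
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
    m
  })
  list(states = states, labels = labels,
       switches = vapply(labels, function(l) sum(diff(l) != 0), 1L))
}

#' GLM prediction of an external stimulus from TVFC estimates
#'
#' Regresses each edge's TVFC time series on an HRF-convolved boxcar
#' stimulus regressor plus polynomial drift terms, the drift order being
#' \code{round(TR * N / 150)}. Coefficients are estimated by ordinary
#' least squares; the stimulus coefficient is reported with one-sided
#' p-values (direction \code{alternative}), Bonferroni corrected over
#' edges.
#'
#' @param tvfc_edges numeric matrix \code{N x G} (one column per edge)
#'   or a vector for a single edge.
#' @param stimulus_boxcar 0/1 vector of length N (stimulus on/off per
#'   volume).
#' @param TR repetition time in seconds.
#' @param alternative direction of the one-sided test on the stimulus
#'   coefficient: \code{"less"} (anticorrelation, default),
#'   \code{"greater"} or \code{"two.sided"}.
#' @return data.frame with one row per edge: \code{edge}, \code{beta},
#'   \code{se}, \code{p}, \code{p_adj}.
#' @export
stimulusGlm <- function(tvfc_edges, stimulus_boxcar, TR,
                        alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  Ymat <- as.matrix(tvfc_edges)
  N <- nrow(Ymat)
  stopifnot(length(stimulus_boxcar) == N)
  h <- hrfDoubleGamma(seq(0, 30, by = TR))
  reg <- as.numeric(stats::convolve(as.numeric(stimulus_boxcar), rev(h),
                                    type = "open"))[seq_len(N)]
  reg <- reg / max(abs(reg))
  order <- max(1L, as.integer(floor(TR * N / 150 + 0.5))) # round half up
  drift <- stats::poly(seq_len(N), degree = order)
  Xd <- cbind(stimulus = reg, intercept = 1, drift)
  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) {
    bad <- setdiff(seq_len(ncol(Xd)), qrX$pivot[seq_len(qrX$rank)])
    stop("rank-deficient design; offending regressor(s): ",
         paste(colnames(Xd)[bad], collapse = ", "))
  }
  G <- ncol(Ymat)
  res <- do.call(rbind, lapply(seq_len(G), function(g) {
    fit <- lm.fit(Xd, Ymat[, g])
    rss <- sum(fit$residuals^2)
    dfres <- N - ncol(Xd)
    XtXinv <- chol2inv(qr.R(qrX))
    se <- sqrt(rss / dfres * XtXinv[1, 1])
    beta <- fit$coefficients["stimulus"]
    tstat <- beta / se
    p <- switch(alternative,
                less = pt(tstat, dfres),
                greater = pt(tstat, dfres, lower.tail = FALSE),
                two.sided = 2 * pt(-abs(tstat), dfres))
    data.frame(edge = g, beta = unname(beta), se = se, p = p)
  }))
  res$p_adj <- pmin(1, res$p * G)
  res
}

# ---- synthetic cohort generators (for exercising the statistics) -----

#' Simulate a synthetic cohort of edge summary vectors
#'
#' Subjects share a loading structure; each subject gets a random effect
#' with variance \code{sigma_X2} per edge, and each session adds
#' independent noise with variance \code{sigma_U2}. Used to exercise the
#' reliability statistics with a known between/within variance ratio.
#'
#' @param S subjects, \code{sessions} sessions, \code{P} edges.
#' @param sigma_X2,sigma_U2 between- and within-subject variances.
#' @param seed RNG seed.
#' @return array \code{S x sessions x P}.
#' @export
simulateCohort <- function(S, sessions, P, sigma_X2 = 3, sigma_U2 = 1,
                           seed = 1L) {
  set.seed(seed)
  subj <- matrix(rnorm(S * P, sd = sqrt(sigma_X2)), S, P)
  out <- array(NA_real_, dim = c(S, sessions, P))
  for (ses in seq_len(sessions))
    out[, ses, ] <- subj + matrix(rnorm(S * P, sd = sqrt(sigma_U2)), S, P)
  out
}

#' Simulate a phenotype linked to a similarity kernel
#'
#' \eqn{y = a + \epsilon} with \eqn{a \sim N(0, \sigma_a^2 K_a)} and
#' \eqn{\epsilon \sim N(0, \sigma_e^2 I)}; the planted morphometricity
#' is \eqn{\sigma_a^2 / (\sigma_a^2 + \sigma_e^2)}.
#'
#' @param Ka similarity kernel.
#' @param sigma_a2,sigma_e2 variance components.
#' @param seed RNG seed.
#' @return numeric phenotype vector.
#' @export
simulateMorphPhenotype <- function(Ka, sigma_a2 = 0.5, sigma_e2 = 0.5,
                                   seed = 1L) {
  S <- nrow(Ka)
  eg <- eigen((Ka + t(Ka)) / 2, symmetric = TRUE)
  R <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  set.seed(seed)
  as.numeric(sqrt(sigma_a2) * (R %*% rnorm(S)) +
             rnorm(S, sd = sqrt(sigma_e2)))
}
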