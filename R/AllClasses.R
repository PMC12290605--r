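#' @import methods
#' @importFrom stats rnorm cor cov sd var optim optimize kmeans
#'   pt arima.sim approx dist lm.fit aggregate
#' @importFrom utils head tail read.delim write.table packageVersion
#' @useDynLib tvfc, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

PROFILE_KINDS <- c("null", "constant", "periodic_slow", "periodic_fast",
                   "stepwise", "state_transition", "boxcar")

#' CovTrajectory: a sequence of covariance/correlation matrices over time
#'
#' Container for a ground-truth or estimated time-varying covariance
#' structure: one symmetric positive semidefinite \code{D x D} matrix per
#' time step.
#'
#' @slot sigmas numeric array, \code{D x D x N}.
#' @slot topology character, one of \code{"bivariate"}, \code{"dense"},
#'   \code{"sparse"} (generators) or \code{"estimate"}.
#' @slot kind character, the generating profile kind or estimator name.
#'
#' @export
setClass("CovTrajectory",
  representation(sigmas = "array", topology = "character", kind = "character"),
  prototype(topology = "estimate", kind = "unknown"))

setValidity("CovTrajectory", function(object) {
  s <- object@sigmas
  if (length(dim(s)) != 3L) return("sigmas must be a D x D x N array")
  if (dim(s)[1] != dim(s)[2]) return("matrices must be square")
  N <- dim(s)[3]
  for (n in seq_len(N)) {
    m <- s[, , n]
    if (max(abs(m - t(m))) > 1e-8) return(sprintf("matrix %d not symmetric", n))
    if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      return(sprintf("matrix %d not positive semidefinite", n))
  }
  TRUE
})

#' TimeSeriesData: a multivariate BOLD-like time series
#'
#' \code{N x D} observation matrix with normalized index locations in
#' \code{[0, 1]} and a repetition time (TR, seconds per volume).
#'
#' @slot Y numeric matrix, \code{N x D}.
#' @slot X numeric vector of length \code{N}, strictly increasing, in
#'   \code{[0, 1]}.
#' @slot TR numeric scalar, seconds per time step.
#' @slot seed integer seed used to generate the data (NA if observed).
#'
#' @export
setClass("TimeSeriesData",
  representation(Y = "matrix", X = "numeric", TR = "numeric",
                 seed = "integer"),
  prototype(TR = 2, seed = NA_integer_))

setValidity("TimeSeriesData", function(object) {
  if (nrow(object@Y) != length(object@X))
    return("length(X) must equal nrow(Y)")
  if (any(diff(object@X) <= 0)) return("X must be strictly increasing")
  if (min(object@X) < 0 || max(object@X) > 1) return("X must lie in [0, 1]")
  if (length(object@TR) != 1 || object@TR <= 0) return("TR must be positive")
  TRUE
})

#' WPModel: a fitted Wishart-process TVFC model
#'
#' Holds the scale-matrix Cholesky factor \code{A}, the diagonal additive
#' noise \code{Lambda}, Matern 5/2 kernel hyperparameters, inducing
#' locations \code{Z} and the whitened variational Gaussians (mean and
#' Cholesky of the covariance) for each of the \code{nu * D} latent GPs.
#'
#' @slot D,nu,M integers: dimension, degrees of freedom, inducing points.
#' @slot A numeric \code{D x D} lower-triangular matrix, positive diagonal.
#' @slot Lambda numeric vector of \code{D} positive noise variances.
#' @slot kernel named numeric vector \code{c(variance=, lengthscale=)}.
#' @slot Z numeric vector of \code{M} inducing locations in \code{[0, 1]}.
#' @slot Vmean numeric \code{M x (D*nu)} matrix of whitened variational means.
#' @slot Vchol numeric \code{M x M x (D*nu)} array of lower-Cholesky factors.
#' @slot trace numeric vector, per-iteration Monte-Carlo ELBO during training.
#' @slot config list, resolved fitting configuration.
#'
#' @export
setClass("WPModel",
  representation(D = "integer", nu = "integer", M = "integer",
                 A = "matrix", Lambda = "numeric", kernel = "numeric",
                 Z = "numeric", Vmean = "matrix", Vchol = "array",
                 trace = "numeric", config = "list"))

setValidity("WPModel", function(object) {
  if (object@nu < object@D) return("nu must be >= D")
  if (any(diag(object@A) <= 0)) return("diag(A) must be positive")
  if (any(object@A[upper.tri(object@A)] != 0))
    return("A must be lower triangular")
  if (any(object@Lambda <= 0)) return("Lambda entries must be positive")
  if (any(object@kernel[c("variance", "lengthscale")] <= 0))
    return("kernel parameters must be positive")
  TRUE
})

setMethod("show", "CovTrajectory", function(object) {
  d <- dim(object@sigmas)
  cat(sprintf("CovTrajectory: D=%d, N=%d, topology=%s, kind=%s\n",
              d[1], d[3], object@topology, object@kind))
})

setMethod("show", "TimeSeriesData", function(object) {
  cat(sprintf("TimeSeriesData: N=%d, D=%d, TR=%gs\n",
              nrow(object@Y), ncol(object@Y), object@TR))
})

setMethod("show", "WPModel", function(object) {
  cat(sprintf(paste0("WPModel: D=%d, nu=%d, M=%d inducing points\n",
                     "  kernel: variance=%.4g lengthscale=%.4g\n",
                     "  final ELBO (MC): %.4f after %d iterations\n"),
              object@D, object@nu, object@M,
              object@kernel["variance"], object@kernel["lengthscale"],
              tail(object@trace, 1), length(object@trace)))
})

# ---- accessors ----

#' @rdname CovTrajectory-class
#' @param object,x a \code{CovTrajectory}, \code{TimeSeriesData} or
#'   \code{WPModel}
#' @export
setGeneric("nTimepoints", function(object) standardGeneric("nTimepoints"))
#' @rdname CovTrajectory-class
#' @export
setGeneric("nNodes", function(object) standardGeneric("nNodes"))
#' @rdname CovTrajectory-class
#' @export
setGeneric("covMatrices", function(object) standardGeneric("covMatrices"))

#' @rdname CovTrajectory-class
#' @export
setMethod("nTimepoints", "CovTrajectory",
          function(object) dim(object@sigmas)[3])
#' @rdname CovTrajectory-class
#' @export
setMethod("nNodes", "CovTrajectory", function(object) dim(object@sigmas)[1])
#' @rdname CovTrajectory-class
#' @export
setMethod("covMatrices", "CovTrajectory", function(object) object@sigmas)
#' @rdname CovTrajectory-class
#' @export
setMethod("nTimepoints", "TimeSeriesData", function(object) nrow(object@Y))
#' @rdname CovTrajectory-class
#' @export
setMethod("nNodes", "TimeSeriesData", function(object) ncol(object@Y))

#' Observation matrix of a TimeSeriesData object
#' @param object a \code{TimeSeriesData}
#' @return numeric \code{N x D} matrix
#' @export
observations <- function(object) object@Y

#' Normalized index locations of a TimeSeriesData object
#' @param object a \code{TimeSeriesData}
#' @return numeric vector in \code{[0, 1]}
#' @export
indexLocations <- function(object) object@X

#' Repetition time (seconds per volume)
#' @param object a \code{TimeSeriesData}
#' @return numeric scalar
#' @export
repetitionTime <- function(object) object@TR

#' Extract the time series of one edge of a trajectory
#'
#' @param traj a \code{CovTrajectory}
#' @param i,j node indices
#' @return numeric vector of length \code{N}
#' @export
edgeSeries <- function(traj, i, j) {
  stopifnot(is(traj, "CovTrajectory"))
  traj@sigmas[i, j, ]
}

newCovTrajectory <- function(sigmas, topology = "estimate",
                             kind = "unknown", validate = TRUE) {
  obj <- new("CovTrajectory", sigmas = sigmas, topology = topology,
             kind = kind)
  if (validate) validObject(obj)
  obj
}

newTimeSeriesData <- function(Y, X = NULL, TR = 2, seed = NA_integer_) {
  Y <- as.matrix(Y)
  if (is.null(X)) X <- normalizedLocations(nrow(Y))
  new("TimeSeriesData", Y = Y, X = as.numeric(X), TR = TR,
      seed = as.integer(seed))
}

#' Normalized index locations for N volumes
#'
#' Maps volume indices \code{1..N} onto \code{[0, 1]} via
#' \code{(n - 1) / (N - 1)}.
#'
#' @param N number of time steps
#' @return numeric vector of length \code{N}
#' @export
normalizedLocations <- function(N) {
  stopifnot(N >= 2)
  (seq_len(N) - 1) / (N - 1)
}
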