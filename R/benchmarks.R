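#' RMSE between estimated and ground-truth correlations
#'
#' For bivariate trajectories the RMSE is computed over the single
#' off-diagonal element across time; for three or more nodes it is
#' computed across all elements of the full correlation matrices
#' (diagonal included — it contributes zero for correlation matrices).
#'
#' @param est,truth [CovTrajectory-class] objects of identical shape.
#' @return non-negative numeric scalar.
#' @export
rmseCorr <- function(est, truth) {
  stopifnot(is(est, "CovTrajectory"), is(truth, "CovTrajectory"))
  if (!all(dim(est@sigmas) == dim(truth@sigmas)))
    stop("trajectory shapes differ")
  D <- nNodes(est)
  if (D == 2) {
    d <- edgeSeries(est, 1, 2) - edgeSeries(truth, 1, 2)
    sqrt(mean(d^2))
  } else {
    sqrt(mean((est@sigmas - truth@sigmas)^2))
  }
}

#' Leave-every-other-out split
#'
#' Alternating assignment of volumes, starting with the training set at
#' the first volume; index locations keep their original positions on
#' \code{[0, 1]}.
#'
#' @param data a [TimeSeriesData-class] with \code{N >= 4}.
#' @return list with \code{train} and \code{test}
#'   ([TimeSeriesData-class]) and the integer index vectors
#'   \code{train_idx}, \code{test_idx}.
#' @export
leooSplit <- function(data) {
  stopifnot(is(data, "TimeSeriesData"))
  N <- nTimepoints(data)
  stopifnot(N >= 4)
  train_idx <- seq.int(1L, N, by = 2L)
  test_idx <- seq.int(2L, N, by = 2L)
  mk <- function(idx) new("TimeSeriesData",
                          Y = observations(data)[idx, , drop = FALSE],
                          X = indexLocations(data)[idx],
                          TR = repetitionTime(data) * 2, seed = data@seed)
  list(train = mk(train_idx), test = mk(test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Linear interpolation of a trajectory at new locations
#'
#' Each matrix element is linearly interpolated between the enclosing
#' training-location estimates (edges clamped to the nearest estimate).
#' Interpolated matrices that fail a PSD check are projected to the
#' nearest correlation matrix; the number of projected steps is reported
#' in attribute \code{"n_projected"}.
#'
#' @param train_traj [CovTrajectory-class] estimated at
#'   \code{train_locs}.
#' @param train_locs,test_locs numeric location vectors in \code{[0, 1]}.
#' @param project project non-PSD interpolants (default TRUE).
#' @return a [CovTrajectory-class] at the test locations.
#' @export
interpolateTrajectory <- function(train_traj, train_locs, test_locs,
                                  project = TRUE) {
  stopifnot(is(train_traj, "CovTrajectory"),
            length(train_locs) == nTimepoints(train_traj))
  D <- nNodes(train_traj)
  Nt <- length(test_locs)
  out <- array(NA_real_, dim = c(D, D, Nt))
  for (i in seq_len(D)) for (j in seq_len(D)) {
    out[i, j, ] <- approx(train_locs, train_traj@sigmas[i, j, ],
                          xout = test_locs, rule = 2)$y
  }
  n_projected <- 0L
  if (project) {
    for (n in seq_len(Nt)) {
      m <- out[, , n]
      ev <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
      if (ev < -1e-10) {
        out[, , n] <- nearestCorrelation(m)
        n_projected <- n_projected + 1L
      }
    }
  }
  traj <- newCovTrajectory(out, kind = train_traj@kind, validate = FALSE)
  attr(traj, "n_projected") <- n_projected
  traj
}

#' Imputation score: mean test log-likelihood
#'
#' Mean over test points of the zero-mean Gaussian log-density of the
#' held-out observation under the method's estimated (correlation-scale)
#' covariance at that point. Singular matrices are projected; points
#' that remain unusable are excluded and counted.
#'
#' @param test_Y \code{N x D} matrix of test observations (or a
#'   [TimeSeriesData-class]).
#' @param test_traj [CovTrajectory-class] of estimates at the test
#'   points.
#' @return numeric scalar with attribute \code{"n_excluded"}.
#' @export
imputationScore <- function(test_Y, test_traj) {
  if (is(test_Y, "TimeSeriesData")) test_Y <- observations(test_Y)
  stopifnot(nrow(test_Y) == nTimepoints(test_traj))
  N <- nrow(test_Y)
  ll <- rep(NA_real_, N)
  for (n in seq_len(N)) {
    S <- test_traj@sigmas[, , n]
    val <- tryCatch(gaussLogLik(test_Y[n, ], S), error = function(e) NULL)
    if (is.null(val)) {
      Sp <- nearestCorrelation(covToCor(S + diag(1e-8, nrow(S))))
      val <- tryCatch(gaussLogLik(test_Y[n, ], Sp + diag(1e-6, nrow(S))),
                      error = function(e) NA_real_)
    }
    ll[n] <- val
  }
  out <- mean(ll, na.rm = TRUE)
  attr(out, "n_excluded") <- sum(is.na(ll))
  out
}

#' TVFC summary measures
#'
#' Edgewise summaries of a TVFC estimate across time: the mean
#' \eqn{\mu_{ij} = \frac{1}{N}\sum_n \Sigma_{n,ij}}, the (population)
#' variance \eqn{\sigma^2_{ij} = \frac{1}{N}\sum_n (\Sigma_{n,ij} -
#' \mu_{ij})^2}, and the rate-of-change
#' \eqn{r_{ij} = \frac{1}{N-1}\sum_{n=2}^N
#' |\Sigma_{n,ij} / \Sigma_{n-1,ij} - 1|}, the mean absolute relative
#' difference between subsequent steps. Rate-of-change terms whose
#' denominator is below \code{eps_guard} in absolute value are skipped
#' (near-null edges make the ratio unstable); the skipped fraction is
#' reported.
#'
#' @param traj a [CovTrajectory-class].
#' @param eps_guard denominator guard for the rate-of-change
#'   (default 1e-3).
#' @return data.frame with one row per edge (i < j): \code{i}, \code{j},
#'   \code{mean}, \code{variance}, \code{rate_of_change},
#'   \code{roc_skipped} (fraction of skipped terms).
#' @export
summaryMeasures <- function(traj, eps_guard = 1e-3) {
  stopifnot(is(traj, "CovTrajectory"), nTimepoints(traj) >= 2)
  D <- nNodes(traj)
  N <- nTimepoints(traj)
  rows <- list()
  for (i in seq_len(D - 1)) for (j in (i + 1):D) {
    s <- edgeSeries(traj, i, j)
    mu <- mean(s)
    v <- mean((s - mu)^2)
    prev <- s[-N]; curr <- s[-1]
    keep <- abs(prev) >= eps_guard
    roc <- if (any(keep))
      sum(abs(curr[keep] / prev[keep] - 1)) / sum(keep) else 0
    rows[[length(rows) + 1L]] <-
      data.frame(i = i, j = j, mean = mu, variance = v,
                 rate_of_change = roc,
                 roc_skipped = 1 - sum(keep) / (N - 1))
  }
  do.call(rbind, rows)
}

# ---- estimator dispatch ----------------------------------------------

#' Estimate a TVFC trajectory with a named method
#'
#' Dispatches on the method name used throughout the benchmarks:
#' \code{"sfc"}, \code{"sw_cv"}, \code{"sw_fixed"}, \code{"dcc_joint"},
#' \code{"dcc_bl"}, or \code{"wp"}.
#'
#' @param data a [TimeSeriesData-class].
#' @param method method name.
#' @param ... method-specific options: \code{omega} (seconds) for
#'   \code{sw_fixed}; \code{grid}, \code{omega_min}, \code{omega_max} for
#'   \code{sw_cv}; \code{M}, \code{max_iter}, \code{lr}, \code{n_mc},
#'   \code{n_samples}, \code{seed} for \code{wp}.
#' @return a [CovTrajectory-class] of correlation estimates at the data
#'   locations. For \code{"wp"} the fitted [WPModel-class] is attached as
#'   attribute \code{"model"}.
#' @export
estimateTvfc <- function(data, method = c("sfc", "sw_cv", "sw_fixed",
                                          "dcc_joint", "dcc_bl", "wp"),
                         ...) {
  method <- match.arg(method)
  opts <- list(...)
  switch(method,
    sfc = sfcTvfc(data),
    sw_cv = do.call(swCvTvfc, c(list(data), opts[names(opts) %in%
      c("grid", "omega_min", "omega_max", "filter")])),
    sw_fixed = {
      omega <- if (!is.null(opts$omega)) opts$omega else 60
      slidingWindowTvfc(data, omega)
    },
    dcc_joint = dccTvfc(data, "joint"),
    dcc_bl = dccTvfc(data, "bivariate_loop"),
    wp = {
      seed <- if (!is.null(opts$seed)) opts$seed else 1L
      M <- if (!is.null(opts$M)) opts$M else 32L
      max_iter <- if (!is.null(opts$max_iter)) opts$max_iter else 5000L
      lr <- if (!is.null(opts$lr)) opts$lr else 0.02
      n_samples <- if (!is.null(opts$n_samples)) opts$n_samples else 1000L
      model <- fitWishartProcess(data, M = M, max_iter = max_iter,
                                 lr = lr, seed = seed)
      traj <- wpTvfc(model, indexLocations(data), n_samples = n_samples,
                     seed = seed)
      attr(traj, "model") <- model
      traj
    })
}

bonferroniPairs <- function(scores_by_method) {
  methods <- names(scores_by_method)
  if (length(methods) < 2) return(NULL)
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  m <- length(pairs)
  do.call(rbind, lapply(pairs, function(pr) {
    a <- scores_by_method[[pr[1]]]; b <- scores_by_method[[pr[2]]]
    ok <- is.finite(a) & is.finite(b)
    tt <- tryCatch(stats::t.test(a[ok], b[ok]), error = function(e) NULL)
    d <- a[ok] - b[ok]
    pooled <- sqrt((var(a[ok]) + var(b[ok])) / 2)
    data.frame(method_a = pr[1], method_b = pr[2],
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p_raw = if (is.null(tt)) NA_real_ else tt$p.value,
               p_adj = if (is.null(tt)) NA_real_
                       else min(1, m * tt$p.value),
               cohens_d = if (pooled > 0) mean(d) / pooled else NA_real_)
  }))
}

#' Simulation recovery benchmark
#'
#' For each covariance structure and trial: simulate data, run each
#' estimation method, and score the RMSE between the estimated and the
#' (noise-adjusted) ground-truth correlations. Methods are compared per
#' structure with two-tailed t-tests on the per-trial RMSEs, Bonferroni
#' corrected over method pairs.
#'
#' @param methods character vector of method names (see
#'   [estimateTvfc()]).
#' @param structures character vector of profile kinds.
#' @param T_trials trials per structure (default 20).
#' @param N time steps per trial (default 400).
#' @param D nodes (default 2).
#' @param snr signal-to-noise ratio or NULL for noiseless data.
#' @param seed base RNG seed; trial t uses \code{seed + t}.
#' @param wp_opts named list of options passed to the WP fit.
#' @return list with \code{scores} (data.frame: method, structure,
#'   trial, score), \code{summary} (mean/SD per method and structure)
#'   and \code{comparisons} (t, Bonferroni-adjusted p, Cohen's d).
#' @export
runSimulationBenchmark <- function(methods = c("sfc", "sw_cv"),
                                   structures = "constant",
                                   T_trials = 20, N = 400, D = 2,
                                   snr = NULL, seed = 1L,
                                   wp_opts = list()) {
  stopifnot(T_trials >= 2)
  rows <- list()
  for (st in structures) {
    for (tr in seq_len(T_trials)) {
      sim <- simulateDataset(st, N = N, D = D, snr = snr,
                             seed = seed + tr)
      for (me in methods) {
        score <- tryCatch({
          est <- if (me == "wp")
            do.call(estimateTvfc,
                    c(list(sim$data, "wp", seed = seed + tr), wp_opts))
          else estimateTvfc(sim$data, me)
          rmseCorr(est, sim$truth)
        }, error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <-
          data.frame(method = me, structure = st, trial = tr,
                     score = score)
      }
    }
  }
  scores <- do.call(rbind, rows)
  summarizeBenchmark(scores)
}

#' Imputation benchmark
#'
#' For each structure and trial: simulate data, split it
#' leave-every-other-out, fit each method on the training half, obtain
#' estimates at the test locations (the Wishart process queries its
#' posterior directly, other methods are linearly interpolated), and
#' score the mean test log-likelihood. Higher is better.
#'
#' @inheritParams runSimulationBenchmark
#' @return as [runSimulationBenchmark()], with test log-likelihood
#'   scores.
#' @export
runImputationBenchmark <- function(methods = c("sfc", "sw_cv"),
                                   structures = "null",
                                   T_trials = 20, N = 400, D = 2,
                                   snr = NULL, seed = 1L,
                                   wp_opts = list()) {
  stopifnot(T_trials >= 2)
  rows <- list()
  for (st in structures) {
    for (tr in seq_len(T_trials)) {
      sim <- simulateDataset(st, N = N, D = D, snr = snr,
                             seed = seed + tr)
      sp <- leooSplit(sim$data)
      test_locs <- indexLocations(sp$test)
      for (me in methods) {
        score <- tryCatch({
          if (me == "wp") {
            fit_opts <- utils::modifyList(
              list(M = 32L, seed = seed + tr), wp_opts)
            model <- do.call(fitWishartProcess,
                             c(list(sp$train), fit_opts))
            test_traj <- wpTvfc(model, test_locs, n_samples = 1000L,
                                seed = seed + tr)
          } else {
            train_est <- estimateTvfc(sp$train, me)
            test_traj <- interpolateTrajectory(train_est,
                                               indexLocations(sp$train),
                                               test_locs)
          }
          as.numeric(imputationScore(sp$test, test_traj))
        }, error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <-
          data.frame(method = me, structure = st, trial = tr,
                     score = score)
      }
    }
  }
  scores <- do.call(rbind, rows)
  summarizeBenchmark(scores)
}

summarizeBenchmark <- function(scores) {
  summary <- aggregate(score ~ method + structure, data = scores,
                       FUN = function(x)
                         c(mean = mean(x, na.rm = TRUE),
                           sd = sd(x, na.rm = TRUE)))
  summary <- cbind(summary[c("method", "structure")],
                   as.data.frame(summary$score))
  comparisons <- do.call(rbind, lapply(split(scores, scores$structure),
    function(df) {
      by_m <- split(df$score, df$method)
      cmp <- bonferroniPairs(by_m)
      if (!is.null(cmp)) cmp$structure <- df$structure[1]
      cmp
    }))
  rownames(comparisons) <- NULL
  list(scores = scores, summary = summary, comparisons = comparisons)
}
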