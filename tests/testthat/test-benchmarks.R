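test_that("rmseCorr matches a brute-force oracle and basic identities", {
  traj8 <- assembleTrajectory(rep(0.8, 20), D = 2)
  traj0 <- assembleTrajectory(rep(0, 20), D = 2)
  expect_equal(rmseCorr(traj8, traj8), 0)
  expect_equal(rmseCorr(traj0, traj8), 0.8)

  set.seed(1)
  for (D in c(2, 3)) {
    a <- array(runif(D * D * 7, -1, 1), c(D, D, 7))
    b <- array(runif(D * D * 7, -1, 1), c(D, D, 7))
    for (n in 1:7) {
      a[, , n] <- (a[, , n] + t(a[, , n])) / 2; diag(a[, , n]) <- 1
      b[, , n] <- (b[, , n] + t(b[, , n])) / 2; diag(b[, , n]) <- 1
    }
    ta <- newCovTrajectory(a, validate = FALSE)
    tb <- newCovTrajectory(b, validate = FALSE)
    expect_equal(rmseCorr(ta, tb), rmseOracle(a, b, D == 2),
                 tolerance = 1e-12)
  }
  expect_error(rmseCorr(traj8, assembleTrajectory(rep(0, 10), D = 2)),
               "shapes")
})

test_that("leave-every-other-out split alternates and conserves indices", {
  d400 <- simulateDataset("null", N = 400, seed = 1)$data
  sp <- leooSplit(d400)
  expect_equal(nTimepoints(sp$train), 200)
  expect_equal(nTimepoints(sp$test), 200)
  expect_equal(sort(c(sp$train_idx, sp$test_idx)), 1:400)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  # original index locations preserved
  expect_equal(indexLocations(sp$train), indexLocations(d400)[sp$train_idx])

  d5 <- newTimeSeriesData(matrix(rnorm(10), 5, 2), TR = 2)
  sp5 <- leooSplit(d5)
  expect_equal(nTimepoints(sp5$train), 3)
  expect_equal(nTimepoints(sp5$test), 2)
})

test_that("trajectory interpolation is linear with clamped edges", {
  M1 <- matrix(c(1, 0.2, 0.2, 1), 2)
  M2 <- matrix(c(1, 0.8, 0.8, 1), 2)
  tr <- newCovTrajectory(array(c(M1, M2), c(2, 2, 2)), validate = FALSE)
  out <- interpolateTrajectory(tr, c(0, 1), c(0, 0.5, 1))
  expect_equal(out@sigmas[, , 1], M1)
  expect_equal(out@sigmas[, , 2], (M1 + M2) / 2)
  expect_equal(out@sigmas[, , 3], M2)

  # adversarial pair: interpolant of PSD 3x3 matrices can break PSD
  A1 <- matrix(c(1, 0.9, -0.9, 0.9, 1, -0.8, -0.9, -0.8, 1), 3)
  A2 <- matrix(c(1, 0.9, 0.9, 0.9, 1, 0.8, 0.9, 0.9, 1), 3)
  A1 <- nearestCorrelation(A1); A2 <- nearestCorrelation(A2)
  attr(A1, "changed") <- NULL; attr(A2, "changed") <- NULL
  tr2 <- newCovTrajectory(array(c(A1, A2), c(3, 3, 2)), validate = FALSE)
  mid <- interpolateTrajectory(tr2, c(0, 1), 0.5)
  ev <- eigen(mid@sigmas[, , 1], symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8) # projection fired if needed
})

test_that("imputation scoring is calibrated against the generating truth", {
  expect_equal(as.numeric(imputationScore(
    matrix(0, 1, 2),
    newCovTrajectory(array(diag(2), c(2, 2, 1)), validate = FALSE))),
    -log(2 * pi))

  # true trajectory outscores an identity trajectory on correlated data
  wins <- 0
  for (s in 1:20) {
    sim <- simulateDataset("periodic_slow", N = 100, seed = 400 + s)
    sp <- leooSplit(sim$data)
    truth_test <- newCovTrajectory(
      sim$truth@sigmas[, , sp$test_idx, drop = FALSE], validate = FALSE)
    ident <- newCovTrajectory(
      array(diag(2), c(2, 2, length(sp$test_idx))), validate = FALSE)
    s_true <- as.numeric(imputationScore(sp$test, truth_test))
    s_id <- as.numeric(imputationScore(sp$test, ident))
    wins <- wins + (s_true > s_id)
  }
  expect_gte(wins, 16)
})

test_that("summary measures obey the defining identities", {
  const <- assembleTrajectory(rep(0.5, 30), D = 2)
  sm <- summaryMeasures(const)
  expect_equal(sm$mean, 0.5)
  expect_identical(sm$variance, 0)
  expect_identical(sm$rate_of_change, 0)

  # hand evaluation of the rate of change: |1.0/0.5 - 1| = 1
  tr <- assembleTrajectory(c(0.5, 1.0), D = 2)
  expect_equal(summaryMeasures(tr)$rate_of_change, 1)

  set.seed(5)
  vals <- runif(50, 0.2, 0.9)
  tr2 <- assembleTrajectory(vals, D = 2)
  sm2 <- summaryMeasures(tr2)
  expect_equal(sm2$mean, mean(vals), tolerance = 1e-12)
  expect_equal(sm2$variance, mean((vals - mean(vals))^2),
               tolerance = 1e-12)
  expect_equal(sm2$roc_skipped, 0)

  # denominator guard engages on near-zero edges
  tiny <- assembleTrajectory(c(1e-6, 0.5, 0.6), D = 2)
  smt <- summaryMeasures(tiny)
  expect_gt(smt$roc_skipped, 0)
})

test_that("simulation benchmark runner scores, compares and reproduces", {
  res <- runSimulationBenchmark(methods = "sfc", structures = "constant",
                                T_trials = 2, N = 120, seed = 5)
  expect_equal(nrow(res$scores), 2)
  expect_true(all(is.finite(res$scores$score)))
  expect_true(all(res$scores$score < 0.15))

  res2 <- runSimulationBenchmark(methods = "sfc", structures = "constant",
                                 T_trials = 2, N = 120, seed = 5)
  expect_identical(res$scores, res2$scores)

  # static truth favors the static estimator
  r_null <- runSimulationBenchmark(methods = "sfc", structures = "null",
                                   T_trials = 10, N = 200, seed = 6)
  r_per <- runSimulationBenchmark(methods = "sfc",
                                  structures = "periodic_slow",
                                  T_trials = 10, N = 200, seed = 6)
  expect_lt(mean(r_null$scores$score), mean(r_per$scores$score))

  # Bonferroni adjustment is monotone and bounded
  res3 <- runSimulationBenchmark(methods = c("sfc", "sw_fixed"),
                                 structures = "constant",
                                 T_trials = 4, N = 150, seed = 7)
  expect_true(all(res3$comparisons$p_adj <= 1))
  expect_true(all(res3$comparisons$p_adj >= res3$comparisons$p_raw))
})

test_that("imputation benchmark reproduces the standalone score", {
  sim <- simulateDataset("periodic_slow", N = 200, seed = 9)
  sp <- leooSplit(sim$data)
  est <- estimateTvfc(sp$train, "sfc")
  manual <- as.numeric(imputationScore(
    sp$test, interpolateTrajectory(est, indexLocations(sp$train),
                                   indexLocations(sp$test))))
  res <- runImputationBenchmark(methods = "sfc",
                                structures = "periodic_slow",
                                T_trials = 2, N = 200, seed = 8)
  expect_equal(res$scores$score[res$scores$trial == 1], manual,
               tolerance = 1e-12)
})
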