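test_that("covariance profiles have the advertised shapes", {
  N <- 400
  expect_equal(covarianceProfile("null", N), rep(0, N))
  expect_equal(covarianceProfile("constant", N), rep(0.8, N))

  slow <- covarianceProfile("periodic_slow", N)
  fast <- covarianceProfile("periodic_fast", N)
  # amplitude 0.8, one vs three full periods
  expect_equal(max(slow), 0.8, tolerance = 1e-3)
  expect_equal(min(slow), -0.8, tolerance = 1e-3)
  n <- 0:(N - 1)
  expect_equal(slow, 0.8 * sin(2 * pi * n / N))
  expect_equal(fast, 0.8 * sin(2 * pi * 3 * n / N))
  # three periods: exact repetition at multiples of N / 3 for divisible N
  fast399 <- covarianceProfile("periodic_fast", 399)
  expect_equal(fast399[1], fast399[1 + 133], tolerance = 1e-6)
  expect_equal(fast399[1], fast399[1 + 266], tolerance = 1e-6)

  step <- covarianceProfile("stepwise", 300)
  expect_equal(length(rle(step)$values), 3) # exactly two change points
  expect_equal(unique(step), c(0, 0.8, -0.6))

  st <- covarianceProfile("state_transition", 400)
  expect_equal(length(rle(st)$values), 8)
  expect_setequal(unique(st), c(0.1, 0.5, -0.3, 0.7))

  box <- covarianceProfile("boxcar", 400)
  expect_equal(max(abs(box)), 0.8, tolerance = 1e-12)
  expect_true(all(abs(box) <= 1))

  expect_error(covarianceProfile("sine", 100), "valid kinds")
})

test_that("assembled trajectories match the generator structure and are PSD", {
  traj <- assembleTrajectory(rep(0.8, 10), D = 2, topology = "bivariate")
  expect_equal(traj@sigmas[, , 5], matrix(c(1, 0.8, 0.8, 1), 2))

  null3 <- assembleTrajectory(rep(0, 4), D = 3, topology = "sparse")
  expect_equal(null3@sigmas[, , 1], diag(3))

  # sparse: only the first two nodes correlated
  sp <- assembleTrajectory(rep(0.7, 3), D = 3, topology = "sparse")
  expect_equal(sp@sigmas[1, 3, 1], 0)
  expect_equal(sp@sigmas[2, 3, 1], 0)
  expect_equal(sp@sigmas[1, 2, 1], 0.7)

  # dense equicorrelation at the PSD boundary stays PSD
  dn <- assembleTrajectory(rep(-1, 3), D = 3, topology = "dense")
  ev <- eigen(dn@sigmas[, , 1], symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  # negative range remapped onto [-0.5, 0], positive kept
  dn2 <- assembleTrajectory(c(-1, -0.5, 0, 0.6, 1), D = 3,
                            topology = "dense")
  expect_equal(dn2@sigmas[1, 2, ], c(-0.5, -0.25, 0, 0.6, 1),
               tolerance = 1e-6)

  # every matrix of every profile kind is PSD across topologies
  for (kind in c("periodic_slow", "stepwise", "state_transition",
                 "boxcar")) {
    prof <- covarianceProfile(kind, 60)
    for (topo in c("dense", "sparse")) {
      tr <- assembleTrajectory(prof, D = 3, topology = topo)
      evs <- apply(tr@sigmas, 3, function(m)
        min(eigen(m, symmetric = TRUE, only.values = TRUE)$values))
      expect_gte(min(evs), -1e-10)
    }
  }

  expect_error(assembleTrajectory(rep(0, 5), D = 3,
                                  topology = "bivariate"), "D = 2")
})

test_that("sampling reproduces the generating correlation and is deterministic", {
  traj0 <- assembleTrajectory(rep(0, 10000), D = 2)
  y0 <- observations(sampleTimeSeries(traj0, seed = 1))
  expect_lt(abs(cor(y0[, 1], y0[, 2])), 0.03)

  traj8 <- assembleTrajectory(rep(0.8, 10000), D = 2)
  y8 <- observations(sampleTimeSeries(traj8, seed = 2))
  expect_equal(cor(y8[, 1], y8[, 2]), 0.8, tolerance = 0.02)

  # z-scored columns
  expect_lt(max(abs(colMeans(y8))), 1e-8)
  expect_lt(max(abs(apply(y8, 2, sd) - 1)), 1e-8)

  again <- observations(sampleTimeSeries(traj8, seed = 2))
  expect_identical(y8, again)
})

test_that("time-resolved sample correlation tracks sigma(n) for every profile", {
  # Monte-Carlo oracle: many replicated draws at a fixed n
  reps <- 4000
  for (kind in c("periodic_slow", "stepwise", "boxcar")) {
    prof <- covarianceProfile(kind, 100)
    picks <- c(20, 55, 90)
    for (n in picks) {
      rho <- prof[n]
      S <- matrix(c(1, rho, rho, 1), 2)
      L <- t(chol(S))
      set.seed(n)
      ys <- t(L %*% matrix(rnorm(2 * reps), 2))
      se <- (1 - rho^2) / sqrt(reps)
      expect_lt(abs(cor(ys[, 1], ys[, 2]) - rho), 4 * se + 1e-3)
    }
  }
})

test_that("surrogate noise has the requested autocorrelation and independence", {
  E0 <- surrogateNoise(5000, 2, ar_coef = 0, seed = 3)
  ac0 <- cor(E0[-1, 1], E0[-5000, 1])
  expect_lt(abs(ac0), 0.05)

  E4 <- surrogateNoise(5000, 2, ar_coef = 0.4, seed = 4)
  ac4 <- cor(E4[-1, 1], E4[-5000, 1])
  expect_lt(abs(ac4 - 0.4), 0.05)
  expect_lt(abs(cor(E4[, 1], E4[, 2])), 0.05)
  # unit marginal variance
  expect_lt(abs(sd(E4[, 1]) - 1), 0.1)

  expect_error(surrogateNoise(100, 2, ar_coef = 1), "stationarity")
})

test_that("noise mixing uses alpha = snr / (1 + snr)", {
  Y <- matrix(1:6, 3, 2)
  E <- matrix(0, 3, 2)
  expect_equal(mixNoise(Y, E, snr = 2)$alpha, 2 / 3)
  expect_equal(mixNoise(Y, E, snr = 1)$alpha, 1 / 2)
  expect_equal(mixNoise(Y, E, snr = 1)$Y, Y / 2)
  # alpha / (1 - alpha) recovers the snr
  a <- mixNoise(Y, E, snr = 5)$alpha
  expect_equal(a / (1 - a), 5, tolerance = 1e-12)
  expect_error(mixNoise(Y, matrix(0, 2, 2), 1), "shape")
})

test_that("ground-truth adjustment matches analytic shrinkage and Monte Carlo", {
  traj <- assembleTrajectory(rep(0.8, 3), D = 2)
  adj <- adjustGroundTruth(traj, alpha = 2 / 3, noise_variances = 1)
  expected <- (4 / 9 * 0.8) / (4 / 9 + 1 / 9)
  expect_equal(adj@sigmas[1, 2, 1], expected, tolerance = 1e-12)
  expect_equal(diag(adj@sigmas[, , 1]), c(1, 1))

  # null stays null; alpha -> 1 leaves correlations unchanged
  null_adj <- adjustGroundTruth(assembleTrajectory(rep(0, 2), D = 2),
                                alpha = 0.5)
  expect_equal(null_adj@sigmas[1, 2, ], c(0, 0))
  near1 <- adjustGroundTruth(traj, alpha = 1 - 1e-9)
  expect_equal(near1@sigmas[1, 2, 1], 0.8, tolerance = 1e-6)

  # Monte-Carlo self-consistency of mixing + adjustment at fixed n
  set.seed(9)
  reps <- 1e5
  rho <- 0.8; alpha <- 2 / 3
  L <- t(chol(matrix(c(1, rho, rho, 1), 2)))
  Ysig <- t(L %*% matrix(rnorm(2 * reps), 2))
  Emix <- matrix(rnorm(2 * reps), reps, 2)
  Ystar <- alpha * Ysig + (1 - alpha) * Emix
  emp <- cor(Ystar[, 1], Ystar[, 2])
  se <- (1 - expected^2) / sqrt(reps)
  expect_lt(abs(emp - expected), 4 * se)
})

test_that("simulateDataset couples data and adjusted truth reproducibly", {
  sim <- simulateDataset("constant", N = 50, seed = 5, snr = 2)
  sim2 <- simulateDataset("constant", N = 50, seed = 5, snr = 2)
  expect_identical(observations(sim$data), observations(sim2$data))
  expect_lt(sim$truth@sigmas[1, 2, 1], 0.8) # noise shrinks the truth
  noiseless <- simulateDataset("constant", N = 50, seed = 5)
  expect_equal(noiseless$truth@sigmas[1, 2, 1], 0.8)
})
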