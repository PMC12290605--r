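test_that("static FC recovers exact and orthogonal cases", {
  y <- rnorm(20)
  same <- cbind(y, y)
  expect_equal(staticFC(same)$cor[1, 2], 1)
  orth <- cbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(staticFC(orth)$cor[1, 2], 0)
  expect_error(staticFC(cbind(rep(1, 5), rnorm(5))), "constant column")
})

test_that("static FC is unbiased for the constant structure over trials", {
  est <- vapply(1:50, function(s) {
    sim <- simulateDataset("constant", N = 400, seed = s)
    staticFC(sim$data)$cor[1, 2]
  }, 1)
  expect_equal(mean(est), 0.8, tolerance = 0.01)
})

test_that("Butterworth high-pass removes DC and keeps the passband", {
  TR <- 2
  N <- 512
  t <- (0:(N - 1)) * TR
  dc <- matrix(5, N, 1)
  out <- highpassFilter(dc, cutoff_hz = 0.02, TR = TR)
  expect_lt(max(abs(out)), 1e-6 * 5)

  f_hi <- 0.2 # well above cutoff 0.02
  s_hi <- matrix(sin(2 * pi * f_hi * t), N, 1)
  out_hi <- highpassFilter(s_hi, 0.02, TR)
  mid <- 100:400
  expect_equal(max(abs(out_hi[mid])), 1, tolerance = 0.05)

  f_lo <- 0.004 # 0.2 x cutoff
  s_lo <- matrix(sin(2 * pi * f_lo * t), N, 1)
  out_lo <- highpassFilter(s_lo, 0.02, TR)
  expect_lt(max(abs(out_lo[mid])), 0.1)

  expect_error(highpassFilter(dc, 0.3, TR), "Nyquist")
})

test_that("sliding-window estimates have the right shape and limits", {
  sim <- simulateDataset("constant", N = 200, seed = 8)
  sw <- slidingWindowTvfc(sim$data, omega = 60)
  expect_equal(nTimepoints(sw), 200)
  expect_true(all(abs(edgeSeries(sw, 1, 2)) <= 1))
  expect_equal(unique(apply(sw@sigmas, 3, function(m) m[1, 1])), 1)

  # identical columns stay perfectly correlated at every step
  y <- rnorm(100)
  d2 <- newTimeSeriesData(cbind(y, y), TR = 2)
  sw2 <- slidingWindowTvfc(d2, omega = 40, filter = FALSE)
  expect_equal(edgeSeries(sw2, 1, 2), rep(1, 100))

  # full-length window, filtering off: the estimate whose window spans
  # all N volumes (zero padding contributes nothing) equals static FC
  swN <- slidingWindowTvfc(sim$data, omega = 200 * 2, filter = FALSE)
  expect_equal(swN@sigmas[1, 2, 101],
               staticFC(sim$data)$cor[1, 2], tolerance = 1e-10)

  expect_error(slidingWindowTvfc(sim$data, omega = 2), "2 volumes")
})

test_that("cross-validated window length responds to the dynamics scale", {
  sim <- simulateDataset("constant", N = 400, seed = 41)
  single <- cvWindowLength(sim$data, grid = 60)
  expect_equal(single$omega, 60)

  # Ne = N minus the largest window (in volumes)
  cv <- cvWindowLength(sim$data)
  expect_equal(cv$n_eval, 400 - round(180 / 2))
  expect_equal(nrow(cv$scores), length(seq(20, 180, by = 4)))

  # constant truth favors long windows, fast dynamics short ones
  longer <- 0
  for (s in 1:6) {
    oc <- cvWindowLength(simulateDataset("constant", N = 400,
                                         seed = 40 + s)$data)$omega
    op <- cvWindowLength(simulateDataset("periodic_fast", N = 400,
                                         seed = 40 + s)$data)$omega
    expect_gte(oc, 20); expect_lte(oc, 180)
    longer <- longer + (oc > op)
  }
  expect_gte(longer, 5)
  # constant data picks from the upper half of the range
  expect_gt(cv$omega, 100)
})

test_that("GARCH(1,1) QML recovers parameters and flags degeneracies", {
  simGarch <- function(N, om, a, b, seed) {
    set.seed(seed)
    h <- om / (1 - a - b)
    y <- numeric(N)
    for (n in seq_len(N)) {
      if (n > 1) h <- om + a * y[n - 1]^2 + b * h
      y[n] <- rnorm(1, sd = sqrt(h))
    }
    y
  }
  # i.i.d. Gaussian data: the ARCH effect vanishes and the
  # unconditional variance matches the sample variance (b alone is not
  # identified when a = 0, since h is then constant for any b)
  set.seed(51)
  y0 <- rnorm(2000, sd = 1.5)
  g0 <- garchFit11(y0)
  expect_lt(g0$a_arch, 0.05)
  expect_equal(g0$uncond_var, var(y0), tolerance = 0.15 * var(y0))

  # parameter recovery within asymptotic uncertainty on most seeds
  hits <- 0
  for (s in 1:5) {
    y <- simGarch(4000, 0.1, 0.1, 0.8, s)
    g <- garchFit11(y)
    ok <- abs(g$a_arch - 0.1) < 0.05 && abs(g$b_garch - 0.8) < 0.12
    hits <- hits + ok
  }
  expect_gte(hits, 4)
  # standardized residuals approximately unit variance
  expect_equal(sd(g0$residuals), 1, tolerance = 0.05)
  expect_error(garchFit11(rep(2, 100)), "constant")
})

test_that("DCC recursion fixed point and PD preservation", {
  set.seed(61)
  Z <- matrix(rnorm(400), 200, 2)
  Qbar <- cor(Z)
  R <- dccRecursion(Z, Qbar, 0, 0)
  for (n in c(1, 50, 200))
    expect_equal(R[, , n], covToCor(Qbar), tolerance = 1e-8,
                 ignore_attr = TRUE)

  # PD preserved along the recursion for random admissible (a, b)
  for (r in 1:5) {
    a <- runif(1, 0, 0.2); b <- runif(1, 0, 0.75)
    Z3 <- matrix(rnorm(300), 100, 3)
    R3 <- dccRecursion(Z3, cor(Z3), a, b)
    evs <- apply(R3, 3, function(m)
      min(eigen(m, symmetric = TRUE, only.values = TRUE)$values))
    expect_gt(min(evs), 0)
  }
})

test_that("DCC estimation recovers a simulated correlation path", {
  simDcc <- function(N, a, b, seed) {
    set.seed(seed)
    Qbar <- matrix(c(1, 0.5, 0.5, 1), 2)
    Q <- Qbar
    R_true <- array(NA_real_, c(2, 2, N))
    Z <- matrix(NA_real_, N, 2)
    z <- rnorm(2)
    for (n in seq_len(N)) {
      if (n > 1) Q <- (1 - a - b) * Qbar + a * tcrossprod(z) + b * Q
      Rn <- covToCor(Q)
      R_true[, , n] <- Rn
      z <- as.numeric(t(chol(Rn)) %*% rnorm(2))
      Z[n, ] <- z
    }
    list(Y = Z, R = R_true)
  }
  sim <- simDcc(4000, 0.05, 0.9, 71)
  est <- dccTvfc(newTimeSeriesData(sim$Y, TR = 2), "joint")
  path_cor <- cor(edgeSeries(est, 1, 2), sim$R[1, 2, ])
  expect_gt(path_cor, 0.7)
})

test_that("joint and bivariate-loop DCC coincide for D = 2", {
  sim <- simulateDataset("periodic_slow", N = 300, seed = 81)
  j <- dccTvfc(sim$data, "joint")
  bl <- dccTvfc(sim$data, "bivariate_loop")
  expect_equal(edgeSeries(j, 1, 2), edgeSeries(bl, 1, 2),
               tolerance = 1e-8)
})

test_that("trivariate DCC assembles pairwise estimates edgewise", {
  sim <- simulateDataset("periodic_slow", N = 300, D = 3,
                         topology = "sparse", seed = 91)
  bl <- dccTvfc(sim$data, "bivariate_loop")
  expect_equal(dim(bl@sigmas), c(3, 3, 300))
  expect_true(all(abs(bl@sigmas) <= 1 + 1e-12))
  expect_equal(bl@sigmas[1, 1, 17], 1)
})
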