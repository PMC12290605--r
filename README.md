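# tvfc: time-varying functional connectivity with Wishart processes

Functional connectivity — the correlation structure between brain-region
activity time series — is usually summarized by a single matrix per
scan. `tvfc` estimates it as a *function of scan time*: given an
`N x D` BOLD-like signal with `y_n ~ N(0, Sigma_n)`, it recovers the
latent covariance trajectory `Sigma_n`. The package is aimed at
researchers comparing TVFC estimation methods and at methodologists who
need a controlled benchmarking harness with known ground truth.

At its core is a **Wishart process** estimator: the covariance is
constructed from `nu * D` latent Gaussian processes `f_{d,k}` over
normalized scan time,

    Sigma_n = A F_n F_n' A' + Lambda,      F_n[d,k] = f_{d,k}(x_n),

with a trainable lower-Cholesky scale factor `A`, diagonal additive
noise `Lambda`, and a shared Matern 5/2 kernel
`k(x,x') = sigma^2 (1 + sqrt(5) r + 5/3 r^2) exp(-sqrt(5) r)`,
`r = |x - x'| / l`. Inference is sparse variational: per-GP Gaussian
variational distributions at `M` inducing points, fitted by maximizing
a reparameterized Monte-Carlo evidence lower bound with Adam
(analytic gradients in an RcppArmadillo core).

Alongside it:

* classical baselines — static FC, sliding window with
  cross-validated window length (held-out Gaussian likelihood over a
  20–180 s grid), and DCC(1,1)-GARCH(1,1) (joint and bivariate-loop,
  two-stage QML);
* a synthetic-data module (seven covariance profiles: null, constant,
  slow/fast periodic, stepwise, state transitions, HRF-convolved
  boxcar; AR(1) surrogate noise mixed at a chosen SNR with the ground
  truth adjusted accordingly);
* benchmarks — RMSE recovery against ground truth and a
  leave-every-other-out imputation task scored by held-out
  log-likelihood;
* downstream statistics — TVFC summary measures (mean, variance,
  rate-of-change), morphometricity via REML variance components,
  edgewise ICC, I2C2, k-means brain states with switch counts, and a
  GLM stimulus-prediction analysis;
* a command-line surface (`inst/scripts/tvfc`) with `simulate`,
  `estimate`, `benchmark`, `summarize`, `states` and `glm`
  subcommands.

See the methods vignette (`vignettes/tvfc-methods.Rmd`) for the model,
its assumptions, and every numerical choice.

## Worked example

Simulate a slowly oscillating bivariate covariance structure with
fMRI-like AR(1) noise at SNR 2, fit the Wishart process, and compare
all estimators against the (noise-adjusted) ground truth:

```r
library(tvfc)
sim <- simulateDataset("periodic_slow", N = 400, D = 2, snr = 2, seed = 1)
model <- fitWishartProcess(sim$data, M = 32, seed = 1)
model
#> WPModel: D=2, nu=2, M=32 inducing points
#>   kernel: variance=0.8168 lengthscale=0.4819
#>   final ELBO (MC): -1106.1449 after 5000 iterations

est <- wpTvfc(model, indexLocations(sim$data), n_samples = 3000, seed = 1)
rmseCorr(est, sim$truth)                      # 0.098
rmseCorr(sfcTvfc(sim$data), sim$truth)        # 0.457
sw <- swCvTvfc(sim$data); attr(sw, "omega")   # 124 (seconds)
rmseCorr(sw, sim$truth)                       # 0.117
rmseCorr(dccTvfc(sim$data, "joint"), sim$truth) # 0.171

summaryMeasures(est)
#>   i j   mean variance rate_of_change roc_skipped
#> 1 1 2 -0.004   0.1813         0.0288      0.0025
```

Reading: the sine-shaped coupling (amplitude shrunk to about 0.69 by
the SNR-2 noise mixing) is tracked by the WP with RMSE 0.098 — less
than half the error of the static estimate (0.457), and ahead of the
cross-validated sliding window (0.117) and DCC (0.171) on this smooth
structure. The summary measures say the same thing: a time-mean near 0
(the sine is symmetric), substantial temporal variance, and a small
rate-of-change, i.e. a smoothly varying estimate.

The learned kernel lengthscale (0.48 of the scan, here about 380 s)
is the model's own answer to the "window length" question that the
sliding-window baseline settles by cross-validation.

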