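// Numerical core for the Wishart-process TVFC estimator and the
// DCC-GARCH baseline. The variational objective (reparameterized
// Monte-Carlo ELBO) and its gradients are computed here; the Adam loop
// lives in R. All latent GPs share one Matern 5/2 kernel and are
// represented in whitened form: u = L_z v with v ~ N(0, I) a priori, so
// the KL term is free of kernel hyperparameters. Kernel-hyperparameter
// gradients chain the analytic gradients w.r.t. the predictive moments
// through central differences of the (cheap) predictive stage.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat matern52_mat(const vec& x, const vec& xp, double kvar,
                        double klen) {
  mat r(x.n_elem, xp.n_elem);
  for (uword i = 0; i < x.n_elem; ++i)
    for (uword j = 0; j < xp.n_elem; ++j)
      r(i, j) = std::abs(x(i) - xp(j)) / klen;
  const double s5 = std::sqrt(5.0);
  return kvar * (1.0 + s5 * r + (5.0 / 3.0) * (r % r)) % exp(-s5 * r);
}

struct Predictive {
  mat Aa;       // M x N whitened cross-weights L_z^{-1} K_zx
  mat Mu;       // N x P predictive means
  mat S2;       // N x P predictive variances (floored)
  umat clamped; // 1 where the variance floor was hit
};

static Predictive wp_predict(const vec& x, const vec& z, double kvar,
                             double klen, const mat& Vm, const cube& Vchol,
                             double jitter, bool need_Aa) {
  const uword N = x.n_elem, P = Vm.n_cols;
  mat Kzz = matern52_mat(z, z, kvar, klen);
  Kzz.diag() += jitter * kvar;
  mat Lz = chol(Kzz, "lower");
  mat Kzx = matern52_mat(z, x, kvar, klen);
  mat Aa = solve(trimatl(Lz), Kzx);
  rowvec qa = sum(Aa % Aa, 0);
  Predictive out;
  out.Mu.set_size(N, P);
  out.S2.set_size(N, P);
  out.clamped.zeros(N, P);
  const double floor_var = 1e-10;
  for (uword j = 0; j < P; ++j) {
    out.Mu.col(j) = Aa.t() * Vm.col(j);
    mat B = Vchol.slice(j).t() * Aa;
    rowvec s2 = kvar - qa + sum(B % B, 0);
    for (uword n = 0; n < N; ++n) {
      if (s2(n) < floor_var) { s2(n) = floor_var; out.clamped(n, j) = 1; }
    }
    out.S2.col(j) = s2.t();
  }
  if (need_Aa) out.Aa = std::move(Aa);
  return out;
}

// in-place lower Cholesky of S (D x D); returns false if not PD
static bool chol_small(const mat& S, mat& L) {
  const uword D = S.n_rows;
  for (uword i = 0; i < D; ++i) {
    for (uword j = 0; j <= i; ++j) {
      double s = S(i, j);
      for (uword k = 0; k < j; ++k) s -= L(i, k) * L(j, k);
      if (i == j) {
        if (s <= 0.0) return false;
        L(i, i) = std::sqrt(s);
      } else {
        L(i, j) = s / L(j, j);
      }
    }
    for (uword j = i + 1; j < D; ++j) L(i, j) = 0.0;
  }
  return true;
}

// [[Rcpp::export]]
Rcpp::List cpp_wp_elbo(const arma::mat& Y, const arma::vec& x,
                       const arma::vec& z, double kvar, double klen,
                       const arma::mat& A, const arma::vec& lambda,
                       const arma::mat& Vm, const arma::cube& Vchol,
                       const arma::cube& eps, double jitter,
                       bool compute_grad, bool kernel_grad) {
  const uword N = Y.n_rows, D = Y.n_cols, M = z.n_elem, P = Vm.n_cols;
  const uword nu = P / D, n_mc = eps.n_slices;
  Predictive pr = wp_predict(x, z, kvar, klen, Vm, Vchol, jitter, true);
  mat Sdev = sqrt(pr.S2);
  const double c0 = -0.5 * double(D) * std::log(2.0 * M_PI);

  mat gMu(N, P, fill::zeros), gS2(N, P, fill::zeros);
  mat gA(D, D, fill::zeros);
  vec glam(D, fill::zeros);
  vec data_samples(n_mc, fill::zeros);

  // preallocated small-matrix workspace
  mat Fn(D, nu), G(D, nu), Sig(D, D), L(D, D), Linv(D, D), Sinv(D, D);
  mat W(D, D), H(D, D), WAH(D, D), gFn(D, nu);
  vec w(D), siy(D);

  for (uword s = 0; s < n_mc; ++s) {
    mat F_all = pr.Mu + Sdev % eps.slice(s);
    double dsum = 0.0;
    for (uword n = 0; n < N; ++n) {
      for (uword k = 0; k < nu; ++k)
        for (uword d = 0; d < D; ++d) Fn(d, k) = F_all(n, k * D + d);
      // G = A * Fn (A lower triangular)
      for (uword k = 0; k < nu; ++k)
        for (uword d = 0; d < D; ++d) {
          double acc = 0.0;
          for (uword c = 0; c <= d; ++c) acc += A(d, c) * Fn(c, k);
          G(d, k) = acc;
        }
      for (uword i = 0; i < D; ++i)
        for (uword j = 0; j <= i; ++j) {
          double acc = 0.0;
          for (uword k = 0; k < nu; ++k) acc += G(i, k) * G(j, k);
          Sig(i, j) = Sig(j, i) = acc;
        }
      Sig.diag() += lambda;
      if (!chol_small(Sig, L)) Rcpp::stop("covariance not PD at step %d",
                                          (int)(n + 1));
      double ldet = 0.0;
      for (uword i = 0; i < D; ++i) ldet += std::log(L(i, i));
      for (uword i = 0; i < D; ++i) {
        double acc = Y(n, i);
        for (uword k = 0; k < i; ++k) acc -= L(i, k) * w(k);
        w(i) = acc / L(i, i);
      }
      dsum += c0 - ldet - 0.5 * dot(w, w);
      if (compute_grad) {
        // Linv (lower), Sinv = Linv' * Linv
        for (uword i = 0; i < D; ++i) {
          Linv(i, i) = 1.0 / L(i, i);
          for (uword j = 0; j < i; ++j) {
            double acc = 0.0;
            for (uword k = j; k < i; ++k) acc -= L(i, k) * Linv(k, j);
            Linv(i, j) = acc / L(i, i);
            Linv(j, i) = 0.0;
          }
        }
        for (uword i = 0; i < D; ++i)
          for (uword j = 0; j <= i; ++j) {
            double acc = 0.0;
            for (uword k = i; k < D; ++k) acc += Linv(k, i) * Linv(k, j);
            Sinv(i, j) = Sinv(j, i) = acc;
          }
        // siy = Sinv * y ; W = -0.5 (Sinv - siy siy')
        for (uword i = 0; i < D; ++i) {
          double acc = 0.0;
          for (uword j = 0; j < D; ++j) acc += Sinv(i, j) * Y(n, j);
          siy(i) = acc;
        }
        for (uword i = 0; i < D; ++i)
          for (uword j = 0; j < D; ++j)
            W(i, j) = -0.5 * (Sinv(i, j) - siy(i) * siy(j));
        for (uword i = 0; i < D; ++i)
          for (uword j = 0; j <= i; ++j) {
            double acc = 0.0;
            for (uword k = 0; k < nu; ++k) acc += Fn(i, k) * Fn(j, k);
            H(i, j) = H(j, i) = acc;
          }
        WAH = W * A * H;
        gA += 2.0 * WAH;
        glam += W.diag();
        gFn = 2.0 * A.t() * W * G;
        for (uword k = 0; k < nu; ++k)
          for (uword d = 0; d < D; ++d) {
            const uword jcol = k * D + d;
            gMu(n, jcol) += gFn(d, k);
            gS2(n, jcol) += gFn(d, k) * eps(n, jcol, s)
                            / (2.0 * Sdev(n, jcol));
          }
      }
    }
    data_samples(s) = dsum;
  }
  double data_term = mean(data_samples);

  // KL between whitened variational posteriors and N(0, I)
  double kl = 0.0;
  mat gVm(M, P, fill::zeros);
  cube gVchol(M, M, P, fill::zeros);
  for (uword j = 0; j < P; ++j) {
    const mat& C = Vchol.slice(j);
    kl += 0.5 * (dot(Vm.col(j), Vm.col(j)) + accu(C % C) - double(M))
        - accu(log(C.diag()));
    if (compute_grad) {
      mat gC = -C; // gradient of the ELBO (= -KL part)
      gC.diag() += 1.0 / C.diag();
      gVchol.slice(j) = trimatl(gC);
      gVm.col(j) = -Vm.col(j);
    }
  }

  double kvar_g = 0.0, klen_g = 0.0;
  if (compute_grad) {
    gMu /= double(n_mc);
    gS2 /= double(n_mc);
    gS2.elem(find(pr.clamped == 1)).zeros(); // variance floor is flat
    gA /= double(n_mc);
    glam /= double(n_mc);
    for (uword j = 0; j < P; ++j) {
      gVm.col(j) += pr.Aa * gMu.col(j);
      mat B = Vchol.slice(j).t() * pr.Aa; // M x N
      mat Aw = pr.Aa.each_row() % gS2.col(j).t();
      gVchol.slice(j) += trimatl(2.0 * Aw * B.t());
    }
    if (kernel_grad) {
      // d(data term)/d(theta) = sum gMu . dMu/dtheta + gS2 . dS2/dtheta,
      // with the predictive-stage derivatives by central differences
      double hv = 1e-5 * (1.0 + std::abs(kvar));
      double hl = 1e-5 * (1.0 + std::abs(klen));
      Predictive pv1 = wp_predict(x, z, kvar + hv, klen, Vm, Vchol,
                                  jitter, false);
      Predictive pv0 = wp_predict(x, z, kvar - hv, klen, Vm, Vchol,
                                  jitter, false);
      kvar_g = (accu(gMu % (pv1.Mu - pv0.Mu))
                + accu(gS2 % (pv1.S2 - pv0.S2))) / (2.0 * hv);
      Predictive pl1 = wp_predict(x, z, kvar, klen + hl, Vm, Vchol,
                                  jitter, false);
      Predictive pl0 = wp_predict(x, z, kvar, klen - hl, Vm, Vchol,
                                  jitter, false);
      klen_g = (accu(gMu % (pl1.Mu - pl0.Mu))
                + accu(gS2 % (pl1.S2 - pl0.S2))) / (2.0 * hl);
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("elbo") = data_term - kl,
    Rcpp::Named("data_term") = data_term,
    Rcpp::Named("kl") = kl,
    Rcpp::Named("elbo_samples") = data_samples - kl,
    Rcpp::Named("gA") = gA,
    Rcpp::Named("glambda") = glam,
    Rcpp::Named("gVmean") = gVm,
    Rcpp::Named("gVchol") = gVchol,
    Rcpp::Named("gkvar") = kvar_g,
    Rcpp::Named("gklen") = klen_g);
}

// [[Rcpp::export]]
Rcpp::List cpp_wp_predictive(const arma::vec& x, const arma::vec& z,
                             double kvar, double klen, const arma::mat& Vm,
                             const arma::cube& Vchol, double jitter) {
  Predictive pr = wp_predict(x, z, kvar, klen, Vm, Vchol, jitter, false);
  return Rcpp::List::create(Rcpp::Named("mu") = pr.Mu,
                            Rcpp::Named("sdev") = sqrt(pr.S2));
}

// Monte-Carlo posterior summaries of the correlation (and covariance)
// trajectory. Uses R's RNG so results are reproducible with set.seed().
// [[Rcpp::export]]
Rcpp::List cpp_wp_posterior(const arma::mat& Mu, const arma::mat& Sdev,
                            const arma::mat& A, const arma::vec& lambda,
                            int D_, int nu_, int n_samples) {
  const uword N = Mu.n_rows, P = Mu.n_cols;
  const uword D = (uword)D_, nu = (uword)nu_, S = (uword)n_samples;
  cube mean_corr(D, D, N, fill::zeros), sd_corr(D, D, N, fill::zeros);
  cube mean_cov(D, D, N, fill::zeros);
  mat Fn(D, nu), G(D, nu), Sig(D, D), R(D, D);
  for (uword n = 0; n < N; ++n) {
    Rcpp::NumericVector rv = Rcpp::rnorm((int)(P * S));
    const double* e = rv.begin();
    mat sum1(D, D, fill::zeros), sum2(D, D, fill::zeros);
    mat sumc(D, D, fill::zeros);
    for (uword s = 0; s < S; ++s) {
      for (uword j = 0; j < P; ++j) {
        const uword d = j % D, k = j / D;
        Fn(d, k) = Mu(n, j) + Sdev(n, j) * e[s * P + j];
      }
      for (uword k = 0; k < nu; ++k)
        for (uword d = 0; d < D; ++d) {
          double acc = 0.0;
          for (uword c = 0; c <= d; ++c) acc += A(d, c) * Fn(c, k);
          G(d, k) = acc;
        }
      for (uword i = 0; i < D; ++i)
        for (uword j = 0; j <= i; ++j) {
          double acc = 0.0;
          for (uword k = 0; k < nu; ++k) acc += G(i, k) * G(j, k);
          Sig(i, j) = Sig(j, i) = acc;
        }
      Sig.diag() += lambda;
      vec sdv = sqrt(Sig.diag());
      for (uword i = 0; i < D; ++i)
        for (uword j = 0; j < D; ++j)
          R(i, j) = Sig(i, j) / (sdv(i) * sdv(j));
      R.diag().ones();
      sum1 += R;
      sum2 += R % R;
      sumc += Sig;
    }
    mat m = sum1 / double(S);
    mat v = sum2 / double(S) - m % m;
    v.elem(find(v < 0)).zeros();
    mean_corr.slice(n) = m;
    sd_corr.slice(n) = sqrt(v);
    mean_cov.slice(n) = sumc / double(S);
  }
  return Rcpp::List::create(Rcpp::Named("mean_corr") = mean_corr,
                            Rcpp::Named("sd_corr") = sd_corr,
                            Rcpp::Named("mean_cov") = mean_cov);
}

// Gaussian quasi-likelihood of a GARCH(1,1) process,
// h_n = omega0 + a * y_{n-1}^2 + b * h_{n-1}, h_1 given.
// [[Rcpp::export]]
Rcpp::List cpp_garch11_nll(const arma::vec& y, double omega0, double a,
                           double b, double h1) {
  const uword N = y.n_elem;
  vec h(N);
  h(0) = h1;
  for (uword n = 1; n < N; ++n)
    h(n) = omega0 + a * y(n - 1) * y(n - 1) + b * h(n - 1);
  double nll = 0.0;
  for (uword n = 0; n < N; ++n)
    nll += 0.5 * (std::log(2.0 * M_PI) + std::log(h(n))
                  + y(n) * y(n) / h(n));
  return Rcpp::List::create(Rcpp::Named("nll") = nll,
                            Rcpp::Named("h") = h);
}

// DCC(1,1) correlation recursion and second-stage quasi-likelihood:
// Q_n = (1 - a - b) Qbar + a z_{n-1} z_{n-1}' + b Q_{n-1}, Q_1 = Qbar,
// R_n = diag(Q_n)^{-1/2} Q_n diag(Q_n)^{-1/2}.
// [[Rcpp::export]]
Rcpp::List cpp_dcc_filter(const arma::mat& Z, const arma::mat& Qbar,
                          double a, double b, bool return_R) {
  const uword N = Z.n_rows, D = Z.n_cols;
  mat Q = Qbar;
  cube R;
  if (return_R) R.set_size(D, D, N);
  double nll = 0.0;
  for (uword n = 0; n < N; ++n) {
    if (n > 0) {
      vec zp = Z.row(n - 1).t();
      Q = (1.0 - a - b) * Qbar + a * (zp * zp.t()) + b * Q;
    }
    vec dq = sqrt(Q.diag());
    mat Rn = Q / (dq * dq.t());
    Rn.diag().ones();
    vec zn = Z.row(n).t();
    double ld, sign;
    log_det(ld, sign, Rn);
    mat Rinv = inv_sympd(symmatu(Rn));
    nll += 0.5 * (ld + dot(zn, Rinv * zn) - dot(zn, zn));
    if (return_R) R.slice(n) = Rn;
  }
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("nll") = nll);
  if (return_R) out["R"] = R;
  return out;
}
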