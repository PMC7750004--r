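// Blocked Gibbs sampler for the hierarchical Gaussian reading-time
// model (one chain). Mirrors the R reference implementation
// (gibbs_lmm_r): crossed participant/item random effects with full
// covariance matrices, half-Normal scale priors, LKJ correlation
// priors via the canonical-partial-correlation parameterization,
// partially collapsed updates for the fixed effects and the residual
// scale, and likelihood-invariant sweep moves. Uses R's RNG so
// results are reproducible from set.seed().

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static double norm1() { return R::norm_rand(); }

// lower-triangular Cholesky factor of a correlation matrix from
// canonical partial correlations w (row-major order i = 2..K, j < i)
static mat cpc_to_chol_cpp(const vec& w, int K) {
  mat L = eye(K, K);
  int idx = 0;
  for (int i = 1; i < K; ++i) {
    double rem = 1.0;
    for (int j = 0; j < i; ++j) {
      L(i, j) = w(idx++) * std::sqrt(rem);
      rem -= L(i, j) * L(i, j);
    }
    L(i, i) = std::sqrt(std::max(rem, 0.0));
  }
  return L;
}

// log prior of unconstrained correlation parameters z inducing
// LKJ(eta), including the tanh Jacobian
static double lkj_cpc_logprior_cpp(const vec& z, int K, double eta) {
  double lp = 0.0;
  int idx = 0;
  for (int i = 1; i < K; ++i) {
    for (int j = 0; j < i; ++j) {
      double w = std::tanh(z(idx++));
      double a = eta + (K - 1 - (j + 1)) / 2.0;
      lp += R::dbeta((w + 1.0) / 2.0, a, a, 1) - std::log(2.0) +
        std::log1p(-w * w);
    }
  }
  return lp;
}

// D(tau) * L_corr from unconstrained theta = (log tau, z)
static mat sigma_chol_cpp(const vec& theta, int p, int q) {
  vec tau = exp(theta.head(p));
  mat L = cpc_to_chol_cpp(tanh(theta.subvec(p, p + q - 1)), p);
  L.each_col([&](vec& col) { col %= tau; });  // row scaling
  return L;
}

// draw from N(Q^{-1} b, Q^{-1}); Q is symmetrized against accumulated
// floating-point asymmetry
static vec draw_mvn_cpp(const mat& Q, const vec& b) {
  mat U = chol(symmatu(Q));               // upper: Q = U'U
  vec m = solve(trimatu(U), solve(trimatl(U.t()), b));
  vec zr(b.n_elem);
  for (uword i = 0; i < zr.n_elem; ++i) zr(i) = norm1();
  return m + solve(trimatu(U), zr);
}

// generic univariate stepping-out slice sampler
template <typename F>
static double slice1(double x0, F logf, double w, int max_steps = 50) {
  double ly = logf(x0) - R::exp_rand();
  double u = R::unif_rand();
  double l = x0 - w * u;
  double r = l + w;
  int s = 0;
  while (logf(l) > ly && s++ < max_steps) l -= w;
  s = 0;
  while (logf(r) > ly && s++ < max_steps) r += w;
  for (;;) {
    double x1 = R::runif(l, r);
    if (logf(x1) >= ly) return x1;
    if (x1 < x0) l = x1; else r = x1;
  }
}

// [[Rcpp::export]]
Rcpp::List gibbs_lmm_chain(const arma::vec& y, const arma::mat& X,
                           const arma::mat& Z,
                           const arma::ivec& pid, const arma::ivec& iid,
                           const arma::uvec& zidx1,
                           const arma::vec& beta_mean,
                           const arma::vec& beta_sd,
                           double re_sd_scale, double sigma_scale,
                           double lkj_eta, int warmup, int iter) {
  const int n = y.n_elem;
  const int pf = X.n_cols;
  const int p = Z.n_cols;
  const int q = p * (p - 1) / 2;
  const int np = pid.max();
  const int ni = iid.max();
  const uvec zidx = zidx1 - 1;           // 0-based random-effect columns

  // per-group crossproducts
  cube Cp(p, p, np, fill::zeros), Ci(p, p, ni, fill::zeros);
  cube XtXi(pf, pf, ni, fill::zeros), ZtXi(p, pf, ni, fill::zeros);
  for (int k = 0; k < n; ++k) {
    const rowvec zk = Z.row(k);
    const rowvec xk = X.row(k);
    Cp.slice(pid(k) - 1) += zk.t() * zk;
    Ci.slice(iid(k) - 1) += zk.t() * zk;
    XtXi.slice(iid(k) - 1) += xk.t() * xk;
    ZtXi.slice(iid(k) - 1) += zk.t() * xk;
  }

  const mat prior_prec = diagmat(1.0 / square(beta_sd));
  const vec prior_mb = beta_mean / square(beta_sd);

  // initialization: least squares + jitter
  vec beta = solve(X, y);
  for (int j = 0; j < pf; ++j) beta(j) += 0.05 * norm1();
  double sigma = stddev(y - X * beta);
  if (!(sigma > 0.05)) sigma = 0.05;
  sigma *= std::exp(0.1 * norm1());
  vec th_p(p + q, fill::zeros), th_i(p + q, fill::zeros);
  for (int j = 0; j < p; ++j) {
    th_p(j) = std::log(0.1) + 0.2 * norm1();
    th_i(j) = std::log(0.1) + 0.2 * norm1();
  }
  mat u_p(np, p, fill::zeros), u_i(ni, p, fill::zeros);

  auto re_logprior = [&](const vec& th) {
    vec ltau = th.head(p);
    vec tau = exp(ltau);
    double lp = p * std::log(2.0) + accu(ltau);
    for (int j = 0; j < p; ++j) lp += R::dnorm(tau(j), 0.0, re_sd_scale, 1);
    return lp + lkj_cpc_logprior_cpp(th.subvec(p, p + q - 1), p, lkj_eta);
  };
  auto re_loglik = [&](const vec& th, const mat& Su, int N) {
    mat Lc = sigma_chol_cpp(th, p, q);
    vec d = Lc.diag();
    if (any(d <= 0)) return -datum::inf;
    mat Linv = inv(trimatl(Lc));
    mat Sinv = Linv.t() * Linv;
    return -N * accu(log(d)) - 0.5 * accu(Sinv % Su);
  };

  mat keep_beta(iter, pf), keep_tau(iter, 2 * p), keep_cor(iter, 2 * q),
      keep_uc(iter, 1 + 2 * (p + q));
  vec keep_sigma(iter);

  for (int t = 0; t < warmup + iter; ++t) {
    double sig2 = sigma * sigma;
    mat Sp_chol = sigma_chol_cpp(th_p, p, q);
    mat Si_chol = sigma_chol_cpp(th_i, p, q);
    mat Lpi = inv(trimatl(Sp_chol));
    mat Lii = inv(trimatl(Si_chol));
    mat Sp_inv = Lpi.t() * Lpi;
    mat Si_inv = Lii.t() * Lii;

    // participant effects
    vec r = y - X * beta;
    for (int k = 0; k < n; ++k)
      r(k) -= dot(Z.row(k), u_i.row(iid(k) - 1));
    mat Bp(np, p, fill::zeros);
    for (int k = 0; k < n; ++k) Bp.row(pid(k) - 1) += Z.row(k) * r(k);
    for (int j = 0; j < np; ++j)
      u_p.row(j) = draw_mvn_cpp(Sp_inv + Cp.slice(j) / sig2,
                                Bp.row(j).t() / sig2).t();

    // fixed effects, item effects integrated out (block Woodbury)
    vec r0 = y;
    for (int k = 0; k < n; ++k)
      r0(k) -= dot(Z.row(k), u_p.row(pid(k) - 1));
    mat B0z(ni, p, fill::zeros);
    mat B0x(ni, pf, fill::zeros);
    for (int k = 0; k < n; ++k) {
      B0z.row(iid(k) - 1) += Z.row(k) * r0(k);
      B0x.row(iid(k) - 1) += X.row(k) * r0(k);
    }
    mat Q = prior_prec;
    vec bvec = prior_mb;
    for (int j = 0; j < ni; ++j) {
      mat Mj = sig2 * Si_inv + Ci.slice(j);
      mat W = solve(Mj, ZtXi.slice(j));
      Q += (XtXi.slice(j) - ZtXi.slice(j).t() * W) / sig2;
      bvec += (B0x.row(j).t() - W.t() * B0z.row(j).t()) / sig2;
    }
    beta = draw_mvn_cpp(Q, bvec);

    // sweep between beta and participant-effect means
    {
      mat Qs = np * Sp_inv.submat(zidx, zidx) + prior_prec;
      vec cu = sum(u_p, 0).t();
      vec scu = Sp_inv * cu;
      vec bs = scu.elem(zidx) - prior_prec * (beta - beta_mean);
      vec delta = draw_mvn_cpp(Qs, bs);
      beta += delta;
      for (uword c = 0; c < zidx.n_elem; ++c) u_p.col(zidx(c)) -= delta(c);
    }

    // mean exchange between the two random-effect blocks
    {
      mat Qd = np * Sp_inv + ni * Si_inv;
      vec bd = Si_inv * sum(u_i, 0).t() - Sp_inv * sum(u_p, 0).t();
      vec delta = draw_mvn_cpp(Qd, bd);
      u_p.each_row() += delta.t();
      u_i.each_row() -= delta.t();
    }

    // residual scale: slice on log sigma, item effects integrated out
    vec r_ni = y - X * beta;
    for (int k = 0; k < n; ++k)
      r_ni(k) -= dot(Z.row(k), u_p.row(pid(k) - 1));
    mat Bi(ni, p, fill::zeros);
    for (int k = 0; k < n; ++k) Bi.row(iid(k) - 1) += Z.row(k) * r_ni(k);
    double rss_ni = dot(r_ni, r_ni);
    double logdet_Si = 2.0 * accu(log(Si_chol.diag()));
    auto sig_target = [&](double ls) {
      double s2 = std::exp(2.0 * ls);
      double ld = 0.0, quad_corr = 0.0;
      for (int j = 0; j < ni; ++j) {
        mat Mj = s2 * Si_inv + Ci.slice(j);
        mat U;
        if (!chol(U, symmatu(Mj))) return -datum::inf;
        ld += 2.0 * accu(log(U.diag()));
        vec wj = solve(trimatu(U), solve(trimatl(U.t()), Bi.row(j).t()));
        quad_corr += dot(Bi.row(j).t(), wj);
      }
      double logdet_V = 2.0 * (n - p * ni) * ls + ni * logdet_Si + ld;
      double s = std::exp(ls);
      return -0.5 * (logdet_V + (rss_ni - quad_corr) / s2) +
        std::log(2.0) + R::dnorm(s, 0.0, sigma_scale, 1) + ls;
    };
    sigma = std::exp(slice1(std::log(sigma), sig_target, 0.3));
    sig2 = sigma * sigma;

    // item effects
    for (int j = 0; j < ni; ++j)
      u_i.row(j) = draw_mvn_cpp(Si_inv + Ci.slice(j) / sig2,
                                Bi.row(j).t() / sig2).t();

    // second residual-scale update, now with the participant effects
    // integrated out (and redrawn below): collapsing each grouping in
    // turn breaks both sigma/random-effect couplings
    vec r_np = y - X * beta;
    for (int k = 0; k < n; ++k)
      r_np(k) -= dot(Z.row(k), u_i.row(iid(k) - 1));
    mat Bp2(np, p, fill::zeros);
    for (int k = 0; k < n; ++k) Bp2.row(pid(k) - 1) += Z.row(k) * r_np(k);
    double rss_np = dot(r_np, r_np);
    double logdet_Sp = 2.0 * accu(log(Sp_chol.diag()));
    auto sig_target_p = [&](double ls) {
      double s2 = std::exp(2.0 * ls);
      double ld = 0.0, quad_corr = 0.0;
      for (int j = 0; j < np; ++j) {
        mat Mj = s2 * Sp_inv + Cp.slice(j);
        mat U;
        if (!chol(U, symmatu(Mj))) return -datum::inf;
        ld += 2.0 * accu(log(U.diag()));
        vec wj = solve(trimatu(U), solve(trimatl(U.t()), Bp2.row(j).t()));
        quad_corr += dot(Bp2.row(j).t(), wj);
      }
      double logdet_V = 2.0 * (n - p * np) * ls + np * logdet_Sp + ld;
      double s = std::exp(ls);
      return -0.5 * (logdet_V + (rss_np - quad_corr) / s2) +
        std::log(2.0) + R::dnorm(s, 0.0, sigma_scale, 1) + ls;
    };
    sigma = std::exp(slice1(std::log(sigma), sig_target_p, 0.3));
    sig2 = sigma * sigma;

    // participant effects redrawn from their full conditional
    for (int j = 0; j < np; ++j)
      u_p.row(j) = draw_mvn_cpp(Sp_inv + Cp.slice(j) / sig2,
                                Bp2.row(j).t() / sig2).t();

    // covariance blocks: component-wise slice on unconstrained scale
    mat Su_p = u_p.t() * u_p;
    for (int j = 0; j < p + q; ++j) {
      auto target = [&](double v) {
        vec th = th_p; th(j) = v;
        return re_loglik(th, Su_p, np) + re_logprior(th);
      };
      th_p(j) = slice1(th_p(j), target, 0.5);
    }
    mat Su_i = u_i.t() * u_i;
    for (int j = 0; j < p + q; ++j) {
      auto target = [&](double v) {
        vec th = th_i; th(j) = v;
        return re_loglik(th, Su_i, ni) + re_logprior(th);
      };
      th_i(j) = slice1(th_i(j), target, 0.5);
    }

    if (t >= warmup) {
      int k = t - warmup;
      keep_beta.row(k) = beta.t();
      keep_sigma(k) = sigma;
      keep_tau(k, span(0, p - 1)) = exp(th_p.head(p)).t();
      keep_tau(k, span(p, 2 * p - 1)) = exp(th_i.head(p)).t();
      mat Rp = cpc_to_chol_cpp(tanh(th_p.subvec(p, p + q - 1)), p);
      mat Ri = cpc_to_chol_cpp(tanh(th_i.subvec(p, p + q - 1)), p);
      Rp = Rp * Rp.t();
      Ri = Ri * Ri.t();
      int idx = 0;
      for (int cc = 0; cc < p; ++cc)
        for (int rr = cc + 1; rr < p; ++rr) {
          keep_cor(k, idx) = Rp(rr, cc);
          keep_cor(k, q + idx) = Ri(rr, cc);
          ++idx;
        }
      keep_uc(k, 0) = std::log(sigma);
      for (int j = 0; j < p + q; ++j) {
        keep_uc(k, 1 + j) = th_p(j);
        keep_uc(k, 1 + p + q + j) = th_i(j);
      }
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("beta") = keep_beta,
    Rcpp::Named("sigma") = keep_sigma,
    Rcpp::Named("tau") = keep_tau,
    Rcpp::Named("cor") = keep_cor,
    Rcpp::Named("uc") = keep_uc);
}
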