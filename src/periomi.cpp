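// Core numerics: paired GEE fit for the joint mean/correlation model, and
// sequential sampling from the conditional linear family (CLF) of joint
// binary distributions.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Pair categories of the correlation model, a pure function of the two
// sites' index attributes:
//   0 different teeth (reference), 1 same tooth, 2 adjacent teeth sharing
//   the same interproximal space, 3 adjacent teeth not sharing it,
//   4 vertically opposing teeth (one maxillary, one mandibular).
static inline int pair_cat(int tooth_j, int ip_j, int jaw_j, int opp_j,
                           int tooth_k, int ip_k, int jaw_k) {
  if (tooth_j == tooth_k) return 1;
  if (jaw_j == jaw_k) {
    if (std::abs(tooth_j - tooth_k) == 1) {
      if (ip_j > 0 && ip_j == ip_k) return 2;
      return 3;
    }
    return 0;
  }
  if (opp_j == tooth_k) return 4;
  return 0;
}

// model correlation for a pair category: alpha on the selected columns of
// the full design (1, same-tooth, adj-same-IP, adj-diff-IP, opposing, logT)
static inline vec e_sub(int cat, double logT, const uvec& cols) {
  vec e(cols.n_elem);
  for (uword t = 0; t < cols.n_elem; ++t) {
    int c = cols[t];
    if (c == 0) e[t] = 1.0;
    else if (c == 5) e[t] = logT;
    else e[t] = (cat == c) ? 1.0 : 0.0;
  }
  return e;
}

// working inverse products: given V (possibly indefinite), compute
// V^{-1} M by Cholesky, with an eigenvalue-floor repair when V is not PD.
static mat solve_spd(const mat& V, const mat& M, double eig_floor) {
  mat L;
  if (chol(L, V, "lower")) {
    return solve(trimatu(L.t()), solve(trimatl(L), M));
  }
  vec d; mat Q;
  eig_sym(d, Q, V);
  d = clamp(d, eig_floor, d.max() > eig_floor ? d.max() : eig_floor);
  return Q * diagmat(1.0 / d) * Q.t() * M;
}

// [[Rcpp::export]]
Rcpp::List gee_engine(const arma::vec& y, const arma::mat& X,
                      const arma::ivec& ptr, const arma::vec& w,
                      const arma::ivec& tooth, const arma::ivec& ip,
                      const arma::ivec& jaw, const arma::ivec& opp,
                      const arma::vec& logT, const arma::uvec& corr_cols,
                      bool fit_alpha, arma::vec beta, arma::vec alpha,
                      double tol, int maxit, double rho_max,
                      double eig_floor) {
  const int K = ptr.n_elem - 1;
  const uword p = X.n_cols;
  const uword q = corr_cols.n_elem;
  const double vmin = 1e-10;

  int iter = 0;
  bool converged = false;
  double max_delta = NA_REAL, max_eta = 0.0;
  double step = 1.0, prev_bdel = datum::inf;

  // per-category correlation for cluster i under current alpha
  auto rho_of = [&](int cat, double lT) {
    double r = 0.0;
    for (uword t = 0; t < q; ++t) {
      int c = corr_cols[t];
      if (c == 0) r += alpha[t];
      else if (c == 5) r += alpha[t] * lT;
      else if (cat == c) r += alpha[t];
    }
    return r;
  };
  bool alpha_zero = !fit_alpha && all(alpha == 0.0);

  for (iter = 1; iter <= maxit; ++iter) {
    // ---- mean-model Fisher scoring step, working covariance from alpha
    mat H(p, p, fill::zeros);
    vec g(p, fill::zeros);
    max_eta = 0.0;
    for (int i = 0; i < K; ++i) {
      int a = ptr[i], n = ptr[i + 1] - ptr[i];
      mat Xi = X.rows(a, a + n - 1);
      vec eta = Xi * beta;
      max_eta = std::max(max_eta, abs(eta).max());
      vec mu = 1.0 / (1.0 + exp(-eta));
      vec v = clamp(mu % (1.0 - mu), vmin, 0.25);
      vec resid = y.subvec(a, a + n - 1) - mu;
      mat D = Xi.each_col() % v;
      if (alpha_zero || n == 1) {
        // independence working covariance: V = diag(v)
        H += w[i] * (Xi.t() * D);            // D' V^{-1} D = X' diag(v) X
        g += w[i] * (Xi.t() * resid);
      } else {
        vec s = sqrt(v);
        double rho5[5];
        for (int c = 0; c < 5; ++c) {
          double r = rho_of(c, logT[i]);
          rho5[c] = std::min(std::max(r, -rho_max), rho_max);
        }
        mat V(n, n);
        for (int jj = 0; jj < n; ++jj) {
          V(jj, jj) = v[jj];
          for (int kk = jj + 1; kk < n; ++kk) {
            int cat = pair_cat(tooth[a + jj], ip[a + jj], jaw[a + jj],
                               opp[a + jj], tooth[a + kk], ip[a + kk],
                               jaw[a + kk]);
            V(jj, kk) = V(kk, jj) = rho5[cat] * s[jj] * s[kk];
          }
        }
        mat RHS(n, p + 1);
        RHS.cols(0, p - 1) = D;
        RHS.col(p) = resid;
        mat sol = solve_spd(V, RHS, eig_floor);
        H += w[i] * (D.t() * sol.cols(0, p - 1));
        g += w[i] * (D.t() * sol.col(p));
      }
    }
    // scoring is not a descent method; damp the step when updates stop
    // contracting (breaks rare period-2 limit cycles)
    vec dbeta = solve(H, g);
    double bdel = abs(dbeta).max();
    if (iter > 3 && bdel > 0.95 * prev_bdel && step > 0.1) step *= 0.5;
    else if (step < 1.0 && bdel < 0.5 * prev_bdel) step = std::min(1.0, 2.0 * step);
    prev_bdel = bdel;
    beta += step * dbeta;
    double del = bdel;   // convergence judged on the full scoring step

    // ---- correlation-model weighted least squares step (working
    //      independence across pairs)
    if (fit_alpha) {
      mat EtE(q, q, fill::zeros);
      vec EtZ(q, fill::zeros);
      for (int i = 0; i < K; ++i) {
        int a = ptr[i], n = ptr[i + 1] - ptr[i];
        if (n < 2) continue;
        mat Xi = X.rows(a, a + n - 1);
        vec mu = 1.0 / (1.0 + exp(-(Xi * beta)));
        vec v = clamp(mu % (1.0 - mu), vmin, 0.25);
        vec r = (y.subvec(a, a + n - 1) - mu) / sqrt(v);
        vec cnt(5, fill::zeros), zsum(5, fill::zeros);
        for (int jj = 0; jj < n; ++jj)
          for (int kk = jj + 1; kk < n; ++kk) {
            int cat = pair_cat(tooth[a + jj], ip[a + jj], jaw[a + jj],
                               opp[a + jj], tooth[a + kk], ip[a + kk],
                               jaw[a + kk]);
            cnt[cat] += 1.0;
            zsum[cat] += r[jj] * r[kk];
          }
        for (int c = 0; c < 5; ++c) {
          if (cnt[c] == 0.0) continue;
          vec e = e_sub(c, logT[i], corr_cols);
          EtE += (w[i] * cnt[c]) * (e * e.t());
          EtZ += (w[i] * zsum[c]) * e;
        }
      }
      vec alpha_new = solve(EtE, EtZ);
      del = std::max(del, abs(alpha_new - alpha).max());
      alpha = alpha_new;
      alpha_zero = false;
    }
    max_delta = del;
    if (del < tol) { converged = true; break; }
  }

  // ---- joint empirical sandwich covariance over clusters at convergence
  mat A11(p, p, fill::zeros);
  mat A21(q, p, fill::zeros), A22(q, q, fill::zeros);
  mat B(p + (fit_alpha ? q : 0), p + (fit_alpha ? q : 0), fill::zeros);
  for (int i = 0; i < K; ++i) {
    int a = ptr[i], n = ptr[i + 1] - ptr[i];
    mat Xi = X.rows(a, a + n - 1);
    vec mu = 1.0 / (1.0 + exp(-(Xi * beta)));
    vec v = clamp(mu % (1.0 - mu), vmin, 0.25);
    vec resid = y.subvec(a, a + n - 1) - mu;
    mat D = Xi.each_col() % v;
    vec Ub(p);
    if (alpha_zero || n == 1) {
      A11 += w[i] * (Xi.t() * D);
      Ub = w[i] * (Xi.t() * resid);
    } else {
      vec s = sqrt(v);
      double rho5[5];
      for (int c = 0; c < 5; ++c) {
        double r = rho_of(c, logT[i]);
        rho5[c] = std::min(std::max(r, -rho_max), rho_max);
      }
      mat V(n, n);
      for (int jj = 0; jj < n; ++jj) {
        V(jj, jj) = v[jj];
        for (int kk = jj + 1; kk < n; ++kk) {
          int cat = pair_cat(tooth[a + jj], ip[a + jj], jaw[a + jj],
                             opp[a + jj], tooth[a + kk], ip[a + kk],
                             jaw[a + kk]);
          V(jj, kk) = V(kk, jj) = rho5[cat] * s[jj] * s[kk];
        }
      }
      mat RHS(n, p + 1);
      RHS.cols(0, p - 1) = D;
      RHS.col(p) = resid;
      mat sol = solve_spd(V, RHS, eig_floor);
      A11 += w[i] * (D.t() * sol.cols(0, p - 1));
      Ub = w[i] * (D.t() * sol.col(p));
    }
    if (!fit_alpha) {
      B.submat(0, 0, p - 1, p - 1) += Ub * Ub.t();
      continue;
    }
    // correlation-equation contribution and cross derivative
    vec r = resid / sqrt(v);
    vec u1m2 = 1.0 - 2.0 * mu;
    vec cnt(5, fill::zeros), zsum(5, fill::zeros);
    mat Sg(5, p, fill::zeros);   // sum over pairs in cat of (u_j + u_k)
    for (int jj = 0; jj < n; ++jj)
      for (int kk = jj + 1; kk < n; ++kk) {
        int cat = pair_cat(tooth[a + jj], ip[a + jj], jaw[a + jj],
                           opp[a + jj], tooth[a + kk], ip[a + kk],
                           jaw[a + kk]);
        cnt[cat] += 1.0;
        zsum[cat] += r[jj] * r[kk];
        Sg.row(cat) += u1m2[jj] * Xi.row(jj) + u1m2[kk] * Xi.row(kk);
      }
    vec Ua(q, fill::zeros);
    for (int c = 0; c < 5; ++c) {
      if (cnt[c] == 0.0) continue;
      double rho = rho_of(c, logT[i]);
      vec e = e_sub(c, logT[i], corr_cols);
      Ua += (w[i] * (zsum[c] - cnt[c] * rho)) * e;
      A22 += (w[i] * cnt[c]) * (e * e.t());
      A21 += (w[i] * rho / 2.0) * (e * Sg.row(c));
    }
    vec U(p + q);
    U.subvec(0, p - 1) = Ub;
    U.subvec(p, p + q - 1) = Ua;
    B += U * U.t();
  }

  mat vcov;
  if (fit_alpha) {
    mat M(p + q, p + q, fill::zeros);
    M.submat(0, 0, p - 1, p - 1) = A11;
    M.submat(p, 0, p + q - 1, p - 1) = A21;
    M.submat(p, p, p + q - 1, p + q - 1) = A22;
    mat Minv = inv(M);
    vcov = Minv * B * Minv.t();
  } else {
    mat Ainv = inv(A11);
    vcov = Ainv * B * Ainv.t();
  }
  vcov = 0.5 * (vcov + vcov.t());

  return Rcpp::List::create(
      Rcpp::Named("beta") = beta, Rcpp::Named("alpha") = alpha,
      Rcpp::Named("vcov") = vcov, Rcpp::Named("iterations") = iter,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("max_delta") = max_delta,
      Rcpp::Named("max_abs_eta") = max_eta);
}

// Sequential CLF draw for one cluster.  `mu` and the site attributes are in
// conditioning order (fixed sites first); `fixed` holds 0/1 for the fixed
// prefix and -1 for positions to draw.  The pairwise correlation is taken
// from `rho` (length 5: reference, same tooth, adjacent same IP, adjacent
// different IP, opposing).  Uses the Cholesky factor of the implied
// covariance so each cluster costs one decomposition; conditional means
// outside [eps, 1-eps] are clamped before drawing (the feasibility repair),
// and their count is reported.
// [[Rcpp::export]]
Rcpp::List clf_draw_engine(const arma::vec& mu_in, const arma::ivec& tooth,
                           const arma::ivec& ip, const arma::ivec& jaw,
                           const arma::ivec& opp, const arma::vec& rho,
                           const arma::ivec& fixed, double eps,
                           double ridge, bool repair) {
  const int n = mu_in.n_elem;
  vec mu = clamp(mu_in, eps, 1.0 - eps);
  vec v = mu % (1.0 - mu);
  vec s = sqrt(v);
  mat Sigma(n, n);
  for (int j = 0; j < n; ++j) {
    Sigma(j, j) = v[j];
    for (int k = j + 1; k < n; ++k) {
      int cat = pair_cat(tooth[j], ip[j], jaw[j], opp[j],
                         tooth[k], ip[k], jaw[k]);
      Sigma(j, k) = Sigma(k, j) = rho[cat] * s[j] * s[k];
    }
  }
  mat L;
  bool ok = chol(L, Sigma, "lower");
  if (!ok) {
    mat S2 = Sigma + ridge * eye(n, n);
    ok = chol(L, S2, "lower");
  }
  if (!ok && repair) {
    vec d; mat Q;
    eig_sym(d, Q, Sigma);
    d = clamp(d, 1e-6, d.max() > 1e-6 ? d.max() : 1e-6);
    ok = chol(L, Q * diagmat(d) * Q.t(), "lower");
  }
  if (!ok) {
    return Rcpp::List::create(Rcpp::Named("ok") = false);
  }

  Rcpp::RNGScope scope;
  vec y(n), vw(n);
  int nclamp = 0, ndraw = 0;
  for (int j = 0; j < n; ++j) {
    double dot = 0.0;
    for (int t = 0; t < j; ++t) dot += L(j, t) * vw[t];
    double lam = mu[j] + dot;
    if (fixed[j] >= 0) {
      y[j] = fixed[j];
    } else {
      double lam_cl = lam;
      if (lam_cl < eps) lam_cl = eps;
      if (lam_cl > 1.0 - eps) lam_cl = 1.0 - eps;
      if (lam_cl != lam) ++nclamp;
      ++ndraw;
      y[j] = (unif_rand() < lam_cl) ? 1.0 : 0.0;
    }
    vw[j] = (y[j] - lam) / L(j, j);
  }
  return Rcpp::List::create(Rcpp::Named("ok") = true,
                            Rcpp::Named("y") = y,
                            Rcpp::Named("n_clamped") = nclamp,
                            Rcpp::Named("n_drawn") = ndraw);
}

// One whole imputation replicate: loops the CLF draw over all clusters
// that have missing sites.  Arrays are stacked in conditioning order
// (observed sites first within each cluster); `fixed` holds 0/1 for
// observed entries and -1 for entries to draw; `rho` is K x 5 per-cluster
// category correlations; `seeds[i]` re-seeds R's RNG before cluster i so
// each (replicate, subject) pair has its own substream.
// [[Rcpp::export]]
Rcpp::List clf_impute_replicate(const arma::vec& mu, const arma::ivec& tooth,
                                const arma::ivec& ip, const arma::ivec& jaw,
                                const arma::ivec& opp, const arma::mat& rho,
                                const arma::ivec& fixed,
                                const arma::ivec& ptr,
                                const arma::ivec& todo,
                                const arma::ivec& seeds, double eps,
                                double ridge) {
  Rcpp::Function set_seed("set.seed");
  const int K = ptr.n_elem - 1;
  vec y = arma::conv_to<vec>::from(fixed);
  long nclamp = 0, ndrawn = 0;
  int fail = -1;
  for (int i = 0; i < K; ++i) {
    if (!todo[i]) continue;
    int a = ptr[i], n = ptr[i + 1] - ptr[i];
    vec mui = clamp(mu.subvec(a, a + n - 1), eps, 1.0 - eps);
    vec v = mui % (1.0 - mui);
    vec s = sqrt(v);
    mat Sigma(n, n);
    for (int jj = 0; jj < n; ++jj) {
      Sigma(jj, jj) = v[jj];
      for (int kk = jj + 1; kk < n; ++kk) {
        int cat = pair_cat(tooth[a + jj], ip[a + jj], jaw[a + jj],
                           opp[a + jj], tooth[a + kk], ip[a + kk],
                           jaw[a + kk]);
        Sigma(jj, kk) = Sigma(kk, jj) = rho(i, cat) * s[jj] * s[kk];
      }
    }
    mat L;
    bool ok = chol(L, Sigma, "lower");
    if (!ok) ok = chol(L, Sigma + ridge * eye(n, n), "lower");
    if (!ok) {
      vec d; mat Q;
      eig_sym(d, Q, Sigma);
      d = clamp(d, 1e-6, d.max() > 1e-6 ? d.max() : 1e-6);
      ok = chol(L, Q * diagmat(d) * Q.t(), "lower");
    }
    if (!ok) { fail = i + 1; break; }
    set_seed(seeds[i]);
    GetRNGstate();
    vec vw(n);
    for (int j = 0; j < n; ++j) {
      double dot = 0.0;
      for (int t = 0; t < j; ++t) dot += L(j, t) * vw[t];
      double lam = mui[j] + dot;
      double yj;
      if (fixed[a + j] >= 0) {
        yj = fixed[a + j];
      } else {
        double lam_cl = std::min(std::max(lam, eps), 1.0 - eps);
        if (lam_cl != lam) ++nclamp;
        ++ndrawn;
        yj = (unif_rand() < lam_cl) ? 1.0 : 0.0;
        y[a + j] = yj;
      }
      vw[j] = (yj - lam) / L(j, j);
    }
    PutRNGstate();
  }
  return Rcpp::List::create(Rcpp::Named("ok") = (fail < 0),
                            Rcpp::Named("fail_cluster") = fail,
                            Rcpp::Named("y") = y,
                            Rcpp::Named("n_clamped") = nclamp,
                            Rcpp::Named("n_drawn") = ndrawn);
}

// Generic CLF sampler for an explicit (mu, R) specification: `ndraws`
// vectors are drawn reusing one Cholesky factor.  Fixed entries (0/1 in
// `fixed`, -1 = free) must occupy a prefix of the conditioning order and
// are identical across draws.
// [[Rcpp::export]]
Rcpp::List clf_draw_sigma_engine(const arma::vec& mu_in, const arma::mat& R,
                                 const arma::ivec& fixed, double eps,
                                 double ridge, bool repair, int ndraws) {
  const int n = mu_in.n_elem;
  vec mu = clamp(mu_in, eps, 1.0 - eps);
  vec v = mu % (1.0 - mu);
  vec s = sqrt(v);
  mat Sigma = R % (s * s.t());
  Sigma.diag() = v;
  mat L;
  bool ok = chol(L, Sigma, "lower");
  if (!ok) ok = chol(L, Sigma + ridge * eye(n, n), "lower");
  if (!ok && repair) {
    vec d; mat Q;
    eig_sym(d, Q, Sigma);
    d = clamp(d, 1e-6, d.max() > 1e-6 ? d.max() : 1e-6);
    ok = chol(L, Q * diagmat(d) * Q.t(), "lower");
  }
  if (!ok) return Rcpp::List::create(Rcpp::Named("ok") = false);

  Rcpp::RNGScope scope;
  mat Y(ndraws, n);
  vec vw(n);
  long nclamp = 0, ndrawn = 0;
  for (int d = 0; d < ndraws; ++d) {
    for (int j = 0; j < n; ++j) {
      double dot = 0.0;
      for (int t = 0; t < j; ++t) dot += L(j, t) * vw[t];
      double lam = mu[j] + dot;
      double yj;
      if (fixed[j] >= 0) {
        yj = fixed[j];
      } else {
        double lam_cl = lam;
        if (lam_cl < eps) lam_cl = eps;
        if (lam_cl > 1.0 - eps) lam_cl = 1.0 - eps;
        if (lam_cl != lam) ++nclamp;
        ++ndrawn;
        yj = (unif_rand() < lam_cl) ? 1.0 : 0.0;
      }
      vw[j] = (yj - lam) / L(j, j);
      Y(d, j) = yj;
    }
  }
  return Rcpp::List::create(Rcpp::Named("ok") = true,
                            Rcpp::Named("y") = Y,
                            Rcpp::Named("n_clamped") = nclamp,
                            Rcpp::Named("n_drawn") = ndrawn);
}

// Category matrix for a set of sites (used by R-side spec construction and
// the exact enumeration oracle).
// [[Rcpp::export]]
arma::imat pair_cat_matrix(const arma::ivec& tooth, const arma::ivec& ip,
                           const arma::ivec& jaw, const arma::ivec& opp) {
  const int n = tooth.n_elem;
  imat C(n, n, fill::zeros);
  for (int j = 0; j < n; ++j)
    for (int k = j + 1; k < n; ++k) {
      int c = pair_cat(tooth[j], ip[j], jaw[j], opp[j],
                       tooth[k], ip[k], jaw[k]);
      C(j, k) = C(k, j) = c;
    }
  return C;
}
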