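// Blocked Gibbs sampler for the joint three-species Gompertz state-space
// model. Species order: 0 cod, 1 capelin, 2 polar cod. Coefficient order per
// species: intercept, own lag, two other-species terms, herring, climate,
// fishing (21 coefficients in total).
//
// One sweep:
//   1. all 21 coefficients | states, Sigma   -- exact GLS normal draw
//   2. latent states | coefficients, Sigma   -- forward filter, backward sample
//   3. sigma_proc (3), r_obs (3), partial correlations (3), anomaly SD
//      | coefficients, states                -- univariate slice updates
//
// All randomness comes from R's RNG so runs are reproducible via set.seed().

#include <RcppArmadillo.h>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Inputs {
  int T;
  mat y;        // T x 3 log observations, NaN = missing
  vec lnH, zST, zIce;
  mat zF;       // T x 3
  int i95;      // 0-based anomaly row, -1 = none
  vec x0mean;
  double x0sd;
  std::vector<uvec> obs_idx;  // observed components per year
};

struct Theta {
  vec sigma;  // process SDs
  vec r;      // obs/proc variance ratios
  vec b;      // partial correlations mapped to (0,1)
  double s95; // extra anomaly-year obs SD
};

struct Prior {
  double a_prec, sig_sd, r_mean, r_sd;
};

mat corr_from_partials(const vec &b) {
  double r12 = 2.0 * b(0) - 1.0, r23 = 2.0 * b(1) - 1.0, p13 = 2.0 * b(2) - 1.0;
  double r13 = p13 * std::sqrt((1.0 - r12 * r12) * (1.0 - r23 * r23)) + r12 * r23;
  mat R = {{1.0, r12, r13}, {r12, 1.0, r23}, {r13, r23, 1.0}};
  return R;
}

mat sigma_mat(const Theta &th) {
  mat R = corr_from_partials(th.b);
  mat D = diagmat(th.sigma);
  return D * R * D;
}

// design matrices of the three structural equations, (T-1) x 7 each
void build_designs(const mat &x, const Inputs &in, mat Z[3]) {
  int n = in.T - 1;
  for (int k = 0; k < 3; ++k) Z[k].set_size(n, 7);
  for (int t = 0; t < n; ++t) {
    // cod: everything at t-1
    Z[0](t, 0) = 1.0; Z[0](t, 1) = x(t, 0); Z[0](t, 2) = x(t, 1);
    Z[0](t, 3) = x(t, 2); Z[0](t, 4) = in.lnH(t); Z[0](t, 5) = in.zST(t);
    Z[0](t, 6) = in.zF(t, 0);
    // capelin: cod and herring current-year, ST and F lagged
    Z[1](t, 0) = 1.0; Z[1](t, 1) = x(t, 1); Z[1](t, 2) = x(t, 2);
    Z[1](t, 3) = x(t + 1, 0); Z[1](t, 4) = in.lnH(t + 1);
    Z[1](t, 5) = in.zST(t); Z[1](t, 6) = in.zF(t, 1);
    // polar cod: cod, herring, ice current-year, F lagged
    Z[2](t, 0) = 1.0; Z[2](t, 1) = x(t, 2); Z[2](t, 2) = x(t, 1);
    Z[2](t, 3) = x(t + 1, 0); Z[2](t, 4) = in.lnH(t + 1);
    Z[2](t, 5) = in.zIce(t + 1); Z[2](t, 6) = in.zF(t, 2);
  }
}

vec rnorm_vec(int n) {
  vec z(n);
  for (int i = 0; i < n; ++i) z(i) = norm_rand();
  return z;
}

// exact GLS draw of the 21 coefficients given states and process precision
vec draw_coefs(const mat &x, const mat &Omega, const Inputs &in, double a_prec) {
  mat Z[3];
  build_designs(x, in, Z);
  mat xr = x.rows(1, in.T - 1);
  mat A(21, 21, fill::zeros);
  vec bvec(21, fill::zeros);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      A.submat(7 * i, 7 * j, 7 * i + 6, 7 * j + 6) = Omega(i, j) * (Z[i].t() * Z[j]);
      bvec.subvec(7 * i, 7 * i + 6) += Omega(i, j) * (Z[i].t() * xr.col(j));
    }
  A.diag() += a_prec;
  mat U = chol(A);  // upper triangular
  vec mu = solve(trimatu(U), solve(trimatl(U.t()), bvec));
  return mu + solve(trimatu(U), rnorm_vec(21));
}

// structural intercept+exogenous parts d (rows 1..T-1 used), lag matrix and
// contemporaneous-cod loading L = I + Gamma
void struct_parts(const vec &a, const Inputs &in, mat &d, mat &A_lag, mat &L) {
  int T = in.T;
  d.set_size(T, 3); d.zeros();
  for (int t = 1; t < T; ++t) {
    d(t, 0) = a(0) + a(4) * in.lnH(t - 1) + a(5) * in.zST(t - 1) + a(6) * in.zF(t - 1, 0);
    d(t, 1) = a(7) + a(11) * in.lnH(t) + a(12) * in.zST(t - 1) + a(13) * in.zF(t - 1, 1);
    d(t, 2) = a(14) + a(18) * in.lnH(t) + a(19) * in.zIce(t) + a(20) * in.zF(t - 1, 2);
  }
  A_lag = {{a(1), a(2), a(3)}, {0.0, a(8), a(9)}, {0.0, a(16), a(15)}};
  L = eye(3, 3);
  L(1, 0) = a(10);   // a_cap_cod
  L(2, 0) = a(17);   // a_pcod_cod
}

mat chol_sym(mat V) {
  V = 0.5 * (V + V.t());
  V.diag() += 1e-12;
  return chol(V);
}

// forward filter, backward sample of the full latent trajectory
mat ffbs(const vec &a, const mat &Sigma, const Theta &th, const Inputs &in) {
  int T = in.T;
  mat d, A_lag, L;
  struct_parts(a, in, d, A_lag, L);
  mat B = L * A_lag;
  mat Q = L * Sigma * L.t();
  mat cc = d * L.t();  // reduced-form intercepts, row t = L * d_t

  mat Rv(T, 3);
  for (int t = 0; t < T; ++t)
    for (int i = 0; i < 3; ++i) Rv(t, i) = th.r(i) * th.sigma(i) * th.sigma(i);
  if (in.i95 >= 0) Rv(in.i95, 2) += th.s95 * th.s95;

  mat m(T, 3);
  cube P(3, 3, T), Pp(3, 3, T);
  mat ap(T, 3, fill::zeros);

  vec mt = in.x0mean;
  mat Pt = eye(3, 3) * (in.x0sd * in.x0sd);
  for (int t = 0; t < T; ++t) {
    if (t > 0) {
      vec apt = cc.row(t).t() + B * mt;
      mat Ppt = B * Pt * B.t() + Q;
      ap.row(t) = apt.t();
      Pp.slice(t) = Ppt;
      mt = apt;
      Pt = Ppt;
    }
    const uvec &obs = in.obs_idx[t];
    if (obs.n_elem > 0) {
      mat S = Pt.submat(obs, obs);
      for (uword k = 0; k < obs.n_elem; ++k) S(k, k) += Rv(t, obs(k));
      mat K = Pt.cols(obs) * inv_sympd(0.5 * (S + S.t()));
      vec yob(obs.n_elem);
      for (uword k = 0; k < obs.n_elem; ++k) yob(k) = in.y(t, obs(k)) - mt(obs(k));
      mt += K * yob;
      Pt -= K * Pt.rows(obs);
    }
    m.row(t) = mt.t();
    P.slice(t) = Pt;
  }

  mat x(T, 3);
  x.row(T - 1) = m.row(T - 1) + rnorm_vec(3).t() * chol_sym(P.slice(T - 1));
  for (int t = T - 2; t >= 0; --t) {
    mat Ppt = 0.5 * (Pp.slice(t + 1) + Pp.slice(t + 1).t());
    Ppt.diag() += 1e-12;
    mat J = P.slice(t) * B.t() * inv_sympd(Ppt);
    vec mu = m.row(t).t() + J * (x.row(t + 1).t() - ap.row(t + 1).t());
    mat V = P.slice(t) - J * Pp.slice(t + 1) * J.t();
    x.row(t) = mu.t() + rnorm_vec(3).t() * chol_sym(V);
  }
  return x;
}

// univariate slice sampler, stepping out + shrinkage (Neal 2003)
double slice1(double x0, const std::function<double(double)> &logf, double w,
              double lower, double upper, int max_steps = 50) {
  double f0 = logf(x0);
  if (!std::isfinite(f0)) Rcpp::stop("slice sampler: non-finite density at current point");
  double z = f0 - exp_rand();
  double u = unif_rand();
  double Lb = x0 - w * u, Rb = Lb + w;
  int j = (int)std::floor(max_steps * unif_rand());
  int k = max_steps - 1 - j;
  while (j > 0 && Lb > lower && logf(std::max(Lb, lower + 1e-12)) > z) { Lb -= w; --j; }
  while (k > 0 && Rb < upper && logf(std::min(Rb, upper - 1e-12)) > z) { Rb += w; --k; }
  Lb = std::max(Lb, lower);
  Rb = std::min(Rb, upper);
  for (int it = 0; it < 1000; ++it) {
    double x1 = Lb + (Rb - Lb) * unif_rand();
    if (logf(x1) > z) return x1;
    if (x1 < x0) Lb = x1; else Rb = x1;
  }
  return x0;
}

Inputs make_inputs(const mat &y, const vec &lnH, const vec &zST,
                   const vec &zIce, const mat &zF, int i95,
                   const vec &x0mean, double x0sd) {
  Inputs in;
  in.T = y.n_rows;
  in.y = y; in.lnH = lnH; in.zST = zST; in.zIce = zIce; in.zF = zF;
  in.i95 = i95 - 1;  // R passes 1-based, 0 = none
  in.x0mean = x0mean; in.x0sd = x0sd;
  in.obs_idx.resize(in.T);
  for (int t = 0; t < in.T; ++t) {
    std::vector<uword> v;
    for (uword i = 0; i < 3; ++i)
      if (!std::isnan(y(t, i))) v.push_back(i);
    in.obs_idx[t] = uvec(v);
  }
  return in;
}

} // namespace

// [[Rcpp::export(name = ".gbs_chain_cpp")]]
Rcpp::List gbs_chain_cpp(const arma::mat &y, const arma::vec &lnH,
                         const arma::vec &zST, const arma::vec &zIce,
                         const arma::mat &zF, int i95,
                         const arma::vec &x0mean, double x0sd,
                         double a_sd, double sigma_sd, double ratio_mean,
                         double ratio_sd, int n_iter, int n_burnin, int thin,
                         const arma::vec &a_init, const arma::vec &sigma_init,
                         const arma::vec &r_init, const arma::vec &b_init,
                         double s95_init, const arma::mat &x_init) {
  Inputs in = make_inputs(y, lnH, zST, zIce, zF, i95, x0mean, x0sd);
  Prior pr{1.0 / (a_sd * a_sd), sigma_sd, ratio_mean, ratio_sd};
  int n_eps = in.T - 1;
  int keep = (n_iter - n_burnin) / thin;

  vec a = a_init;
  Theta th{sigma_init, r_init, b_init, s95_init};
  mat x = x_init;

  mat params(keep, 31);
  cube states(in.T, 3, keep);
  ivec iters(keep);

  mat SE(3, 3);
  vec ss(3), nobs(3);
  double e95 = datum::nan;

  // process and observation log likelihoods as functions of theta, with the
  // sufficient statistics (SE, ss, e95) held fixed within a sweep
  auto proc_ll = [&](const Theta &t) {
    mat S = sigma_mat(t);
    double ld, sign;
    log_det(ld, sign, S);
    if (sign <= 0) return -datum::inf;
    mat Oi = inv_sympd(0.5 * (S + S.t()));
    return -0.5 * n_eps * ld - 0.5 * accu(Oi % SE);
  };
  auto obs_ll = [&](const Theta &t) {
    double ll = 0.0;
    for (int i = 0; i < 3; ++i) {
      double v = t.r(i) * t.sigma(i) * t.sigma(i);
      ll += -0.5 * nobs(i) * std::log(v) - ss(i) / (2.0 * v);
    }
    if (std::isfinite(e95)) {
      double v95 = t.r(2) * t.sigma(2) * t.sigma(2) + t.s95 * t.s95;
      ll += -0.5 * std::log(v95) - e95 * e95 / (2.0 * v95);
    }
    return ll;
  };

  int kept = 0;
  for (int it = 1; it <= n_iter; ++it) {
    mat Sigma = sigma_mat(th);
    mat Omega = inv_sympd(0.5 * (Sigma + Sigma.t()));

    a = draw_coefs(x, Omega, in, pr.a_prec);
    x = ffbs(a, Sigma, th, in);

    // sufficient statistics for the scalar updates
    mat Z[3];
    build_designs(x, in, Z);
    mat E(n_eps, 3);
    for (int i = 0; i < 3; ++i)
      E.col(i) = x.submat(1, i, in.T - 1, i) - Z[i] * a.subvec(7 * i, 7 * i + 6);
    SE = E.t() * E;
    e95 = datum::nan;
    for (int i = 0; i < 3; ++i) {
      double s = 0.0; int n = 0;
      for (int t = 0; t < in.T; ++t) {
        if (std::isnan(in.y(t, i))) continue;
        double r = in.y(t, i) - x(t, i);
        if (i == 2 && t == in.i95) { e95 = r; continue; }
        s += r * r; ++n;
      }
      ss(i) = s; nobs(i) = n;
    }

    // two scans of the scalar block per sweep: the correlation parameters
    // are the slowest-mixing components and the scans are cheap relative to
    // the coefficient and state draws
    for (int scan = 0; scan < 2; ++scan) {
    for (int i = 0; i < 3; ++i) {
      th.sigma(i) = slice1(th.sigma(i), [&](double v) {
        Theta t2 = th; t2.sigma(i) = v;
        return proc_ll(t2) + obs_ll(t2) + R::dnorm(v, 0.0, pr.sig_sd, 1);
      }, 0.1, 1e-8, datum::inf);
      th.r(i) = slice1(th.r(i), [&](double v) {
        Theta t2 = th; t2.r(i) = v;
        return obs_ll(t2) + R::dnorm(v, pr.r_mean, pr.r_sd, 1);
      }, 0.5, 1e-8, datum::inf);
    }
    for (int k = 0; k < 3; ++k) {
      double al = (k == 2) ? 1.0 : 1.5;  // lag-1 partials vs the (1,3) partial
      th.b(k) = slice1(th.b(k), [&](double v) {
        Theta t2 = th; t2.b(k) = v;
        return proc_ll(t2) + R::dbeta(v, al, al, 1);
      }, 0.2, 1e-10, 1.0 - 1e-10);
    }
    if (in.i95 >= 0) {
      th.s95 = slice1(th.s95, [&](double v) {
        Theta t2 = th; t2.s95 = v;
        return obs_ll(t2) + R::dnorm(v, 0.0, pr.sig_sd, 1);
      }, 0.5, 1e-8, datum::inf);
    }
    }

    if (it > n_burnin && (it - n_burnin) % thin == 0) {
      mat R = corr_from_partials(th.b);
      params.submat(kept, 0, kept, 20) = a.t();
      params(kept, 21) = th.sigma(0); params(kept, 22) = th.sigma(1);
      params(kept, 23) = th.sigma(2);
      params(kept, 24) = th.r(0); params(kept, 25) = th.r(1);
      params(kept, 26) = th.r(2);
      params(kept, 27) = R(0, 1); params(kept, 28) = R(1, 2);
      params(kept, 29) = R(0, 2);
      // without an anomaly year the extra observation SD is not a model
      // parameter; record 0 so it cannot pollute convergence summaries
      params(kept, 30) = (in.i95 >= 0) ? th.s95 : 0.0;
      states.slice(kept) = x;
      iters(kept) = it;
      ++kept;
    }
    if (it % 512 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("params") = params,
                            Rcpp::Named("states") = states,
                            Rcpp::Named("iter") = iters);
}

// repeated GLS coefficient draws at fixed states/covariance (used by the
// conditional-distribution oracle tests)
// [[Rcpp::export(name = ".gbs_draw_coefs_cpp")]]
arma::mat gbs_draw_coefs_cpp(const arma::mat &x, const arma::mat &Sigma,
                             const arma::mat &y, const arma::vec &lnH,
                             const arma::vec &zST, const arma::vec &zIce,
                             const arma::mat &zF, int i95,
                             const arma::vec &x0mean, double x0sd,
                             double a_sd, int n) {
  Inputs in = make_inputs(y, lnH, zST, zIce, zF, i95, x0mean, x0sd);
  mat Omega = inv_sympd(Sigma);
  mat out(n, 21);
  for (int s = 0; s < n; ++s)
    out.row(s) = draw_coefs(x, Omega, in, 1.0 / (a_sd * a_sd)).t();
  return out;
}

// repeated FFBS latent-state draws at fixed parameters (oracle tests)
// [[Rcpp::export(name = ".gbs_ffbs_cpp")]]
arma::cube gbs_ffbs_cpp(const arma::vec &a, const arma::mat &Sigma,
                        const arma::vec &r_obs, double s95,
                        const arma::mat &y, const arma::vec &lnH,
                        const arma::vec &zST, const arma::vec &zIce,
                        const arma::mat &zF, int i95,
                        const arma::vec &x0mean, double x0sd, int n) {
  Inputs in = make_inputs(y, lnH, zST, zIce, zF, i95, x0mean, x0sd);
  Theta th{sqrt(Sigma.diag()), r_obs / 1.0, {0.5, 0.5, 0.5}, s95};
  // r_obs in Theta is only used through r(i)*sigma(i)^2 in ffbs; rescale so
  // that product equals the requested observation variances
  for (int i = 0; i < 3; ++i) th.r(i) = r_obs(i);
  cube out(in.T, 3, n);
  for (int s = 0; s < n; ++s) out.slice(s) = ffbs(a, Sigma, th, in);
  return out;
}
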