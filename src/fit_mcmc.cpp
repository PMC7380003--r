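// MCMC sampler for the joint model with interval-censored event times.
//
// Likelihood per patient i (random effects b_i, parameters theta):
//   prod_j t_nu( (y_ij - x_ij'beta - z_ij'b_i) / sigma ) / sigma
//   * [ S(0->l_i | b_i) - S(0->r_i | b_i) ]   if the event interval is observed
//   * [ S(0->l_i | b_i) ]                     if right-censored at l_i
//   * N(b_i; 0, D)
// with S(0->t|b) = exp(-Lambda), Lambda evaluated by fixed Gauss-Legendre
// nodes precomputed in R, and a Weibull baseline hazard.
//
// Updates: adaptive random-walk Metropolis — block proposals for beta and
// gamma (shaped by their least-squares covariance), scalars for the
// association/log-scale parameters, per-patient blocks scaled by chol(D)
// for the b_i; a conjugate inverse-Wishart Gibbs step for D; and a
// likelihood-invariant translation move along the nested-spline ridge
// shared by beta and the random effects.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct FitData {
  vec y; mat X, Z; uvec obs_s, obs_e;          // per-patient row ranges
  vec wL, lognodL; mat XL, ZL, XLv, ZLv; uvec l_s, l_e;
  vec wR, lognodR; mat XR, ZR, XRv, ZRv; uvec r_s, r_e;
  uvec event; mat W;                            // n x 2 baseline covariates
  uvec pid_obs, pidL, pidR;                     // row -> patient maps
  int n, p, q;
  double nu;
  double sd_beta, sd_assoc, sd_logsigma, sd_logwb;
};

static uvec ranges_to_pid(const uvec& s, const uvec& e, uword nrow) {
  uvec pid(nrow);
  for (uword i = 0; i < s.n_elem; ++i)
    for (uword r = s(i); r < e(i); ++r) pid(r) = i;
  return pid;
}

struct FitState {
  vec beta, gamma; double a1, a2, logsigma, logk, loglam;
  mat b;            // n x q
  mat D, Dinv, Ld;  // Ld = lower chol of D
};

// t log-density sum for rows [s, e) given current beta and b_i
static double obs_ll_patient(const FitData& d, const FitState& st, int i) {
  double sigma = std::exp(st.logsigma);
  double s2nu = d.nu * sigma * sigma;
  double out = 0.0;
  for (uword r = d.obs_s(i); r < d.obs_e(i); ++r) {
    double m = dot(d.X.row(r), st.beta) + dot(d.Z.row(r), st.b.row(i));
    double res = d.y(r) - m;
    out += -std::log(sigma) - 0.5 * (d.nu + 1.0) * std::log1p(res * res / s2nu);
  }
  return out;
}

// Lambda(0 -> t) over rows [s, e) of a node block
static double lam_block(const FitData& d, const FitState& st, int i,
                        const vec& w, const vec& lognod, const mat& Xn,
                        const mat& Zn, const mat& Xnv, const mat& Znv,
                        uword s, uword e) {
  double k = std::exp(st.logk);
  double eta0 = st.logk - st.loglam + dot(d.W.row(i), st.gamma);
  double out = 0.0;
  for (uword r = s; r < e; ++r) {
    double m = dot(Xn.row(r), st.beta) + dot(Zn.row(r), st.b.row(i));
    double mv = dot(Xnv.row(r), st.beta) + dot(Znv.row(r), st.b.row(i));
    double lh = eta0 + (k - 1.0) * (lognod(r) - st.loglam) +
                st.a1 * m + st.a2 * mv;
    out += w(r) * std::exp(lh);
  }
  return out;
}

static double surv_ll_patient(const FitData& d, const FitState& st, int i) {
  double lamL = (d.l_e(i) > d.l_s(i))
    ? lam_block(d, st, i, d.wL, d.lognodL, d.XL, d.ZL, d.XLv, d.ZLv,
                d.l_s(i), d.l_e(i)) : 0.0;
  if (!d.event(i)) return -lamL;
  double lamR = lam_block(d, st, i, d.wR, d.lognodR, d.XR, d.ZR, d.XRv,
                          d.ZRv, d.r_s(i), d.r_e(i));
  double diff = lamR - lamL;
  if (diff <= 0) return -1e10;          // numerically invalid ordering
  // log( exp(-lamL) - exp(-lamR) )
  return -lamL + std::log1p(-std::exp(-diff));
}

static double data_ll_patient(const FitData& d, const FitState& st, int i) {
  return obs_ll_patient(d, st, i) + surv_ll_patient(d, st, i);
}

// Vectorized full-data pass: one matrix op per block, per-patient sums
// accumulated through the row ranges.
static double data_ll_total(const FitData& d, const FitState& st, vec& pll) {
  pll.zeros(d.n);
  double sigma = std::exp(st.logsigma);
  double s2nu = d.nu * sigma * sigma;
  double k = std::exp(st.logk);

  if (d.y.n_elem > 0) {
    vec r = d.y - d.X * st.beta - sum(d.Z % st.b.rows(d.pid_obs), 1);
    vec llv = -std::log(sigma) - 0.5 * (d.nu + 1.0) *
      log1p(square(r) / s2nu);
    for (uword rr = 0; rr < llv.n_elem; ++rr) pll(d.pid_obs(rr)) += llv(rr);
  }

  vec eta0 = st.logk - st.loglam + d.W * st.gamma;   // per patient

  auto lam_all = [&](const vec& w, const vec& lognod, const mat& Xn,
                     const mat& Zn, const mat& Xnv, const mat& Znv,
                     const uvec& pid, vec& lam) {
    lam.zeros(d.n);
    if (w.n_elem == 0) return;
    mat Bg = st.b.rows(pid);
    vec lh = (k - 1.0) * (lognod - st.loglam) + eta0(pid) +
      st.a1 * (Xn * st.beta + sum(Zn % Bg, 1)) +
      st.a2 * (Xnv * st.beta + sum(Znv % Bg, 1));
    vec hw = w % exp(lh);
    for (uword rr = 0; rr < hw.n_elem; ++rr) lam(pid(rr)) += hw(rr);
  };

  vec lamL, lamR;
  lam_all(d.wL, d.lognodL, d.XL, d.ZL, d.XLv, d.ZLv, d.pidL, lamL);
  lam_all(d.wR, d.lognodR, d.XR, d.ZR, d.XRv, d.ZRv, d.pidR, lamR);

  for (int i = 0; i < d.n; ++i) {
    if (!d.event(i)) {
      pll(i) += -lamL(i);
    } else {
      double diff = lamR(i) - lamL(i);
      pll(i) += (diff <= 0) ? -1e10
        : -lamL(i) + std::log1p(-std::exp(-diff));
    }
  }
  return accu(pll);
}

static double theta_logprior(const FitData& d, const FitState& st) {
  double lp = 0.0;
  lp += -0.5 * dot(st.beta, st.beta) / (d.sd_beta * d.sd_beta);
  lp += -0.5 * dot(st.gamma, st.gamma) / (d.sd_assoc * d.sd_assoc);
  lp += -0.5 * (st.a1 * st.a1 + st.a2 * st.a2) / (d.sd_assoc * d.sd_assoc);
  lp += -0.5 * st.logsigma * st.logsigma / (d.sd_logsigma * d.sd_logsigma);
  lp += -0.5 * (st.logk * st.logk + st.loglam * st.loglam) /
        (d.sd_logwb * d.sd_logwb);
  return lp;
}

static mat riwish(double df, const mat& S) {
  // inverse-Wishart(df, S): D = W^{-1}, W ~ Wishart(df, S^{-1})
  int q = S.n_rows;
  mat L = chol(inv_sympd(S), "lower");
  mat A(q, q, fill::zeros);
  for (int i = 0; i < q; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::rnorm(0.0, 1.0);
  }
  mat LA = L * A;
  mat Wm = LA * LA.t();
  return inv_sympd(Wm);
}

// [[Rcpp::export(name = ".cpp_fit_mcmc")]]
Rcpp::List cpp_fit_mcmc(const Rcpp::List& data, const Rcpp::List& init,
                        const int niter, const int nburn, const int thin) {
  FitData d;
  d.y = Rcpp::as<vec>(data["y"]);
  d.X = Rcpp::as<mat>(data["X"]); d.Z = Rcpp::as<mat>(data["Z"]);
  d.obs_s = Rcpp::as<uvec>(data["obs_s"]); d.obs_e = Rcpp::as<uvec>(data["obs_e"]);
  d.wL = Rcpp::as<vec>(data["wL"]); d.lognodL = Rcpp::as<vec>(data["lognodL"]);
  d.XL = Rcpp::as<mat>(data["XL"]); d.ZL = Rcpp::as<mat>(data["ZL"]);
  d.XLv = Rcpp::as<mat>(data["XLv"]); d.ZLv = Rcpp::as<mat>(data["ZLv"]);
  d.l_s = Rcpp::as<uvec>(data["l_s"]); d.l_e = Rcpp::as<uvec>(data["l_e"]);
  d.wR = Rcpp::as<vec>(data["wR"]); d.lognodR = Rcpp::as<vec>(data["lognodR"]);
  d.XR = Rcpp::as<mat>(data["XR"]); d.ZR = Rcpp::as<mat>(data["ZR"]);
  d.XRv = Rcpp::as<mat>(data["XRv"]); d.ZRv = Rcpp::as<mat>(data["ZRv"]);
  d.r_s = Rcpp::as<uvec>(data["r_s"]); d.r_e = Rcpp::as<uvec>(data["r_e"]);
  d.event = Rcpp::as<uvec>(data["event"]);
  d.W = Rcpp::as<mat>(data["W"]);
  d.n = Rcpp::as<int>(data["n"]); d.p = Rcpp::as<int>(data["p"]);
  d.q = Rcpp::as<int>(data["q"]);
  d.nu = Rcpp::as<double>(data["nu"]);
  d.pid_obs = ranges_to_pid(d.obs_s, d.obs_e, d.y.n_elem);
  d.pidL = ranges_to_pid(d.l_s, d.l_e, d.wL.n_elem);
  d.pidR = ranges_to_pid(d.r_s, d.r_e, d.wR.n_elem);
  d.sd_beta = Rcpp::as<double>(data["sd_beta"]);
  d.sd_assoc = Rcpp::as<double>(data["sd_assoc"]);
  d.sd_logsigma = Rcpp::as<double>(data["sd_logsigma"]);
  d.sd_logwb = Rcpp::as<double>(data["sd_logwb"]);

  FitState st;
  st.beta = Rcpp::as<vec>(init["beta"]);
  st.gamma = Rcpp::as<vec>(init["gamma"]);
  st.a1 = Rcpp::as<double>(init["a1"]);
  st.a2 = Rcpp::as<double>(init["a2"]);
  st.logsigma = std::log(Rcpp::as<double>(init["sigma"]));
  st.logk = std::log(Rcpp::as<double>(init["shape"]));
  st.loglam = std::log(Rcpp::as<double>(init["scale"]));
  st.b = Rcpp::as<mat>(init["b"]);
  st.D = Rcpp::as<mat>(init["D"]);
  st.Dinv = inv_sympd(st.D);
  st.Ld = chol(st.D, "lower");

  // proposal shapes for the correlated coefficient blocks
  mat Lbeta = Rcpp::as<mat>(data["Lbeta"]);    // p x p lower
  mat Lgamma = Rcpp::as<mat>(data["Lgamma"]);  // 2 x 2 lower
  // projection of the random-effects basis onto the fixed design (the
  // random natural-spline space is nested in the fixed one), used by the
  // likelihood-invariant translation move b_i -> b_i - delta,
  // beta -> beta + A delta
  mat Atr = Rcpp::as<mat>(data["Atr"]);        // p x q

  // blocks: 0 = beta, 1 = gamma, then a1, a2, logsigma, logk, loglam
  const int nblk = 7;
  vec step = {0.5, 0.5, 0.05, 0.1, 0.05, 0.05, 0.05};
  vec bstep(d.n, fill::value(0.6));
  ivec acc_theta(nblk, fill::zeros), try_theta(nblk, fill::zeros);
  ivec acc_b(d.n, fill::zeros), try_b(d.n, fill::zeros);
  const int ntheta = d.p + 2 + 2 + 3;   // flat draw storage layout

  vec cur_pll;
  double cur_ll = data_ll_total(d, st, cur_pll);

  int nkeep = (niter - nburn) / thin;
  mat out_theta(nkeep, ntheta);
  cube out_D(d.q, d.q, nkeep);
  mat out_bmean(nkeep, d.q);
  int keep = 0;

  Rcpp::RNGScope scope;
  double prior_df = d.q + 2.0;
  mat prior_S = eye(d.q, d.q);

  auto get_theta = [&](int j) -> double& {
    if (j < d.p) return st.beta(j);
    if (j < d.p + 2) return st.gamma(j - d.p);
    if (j == d.p + 2) return st.a1;
    if (j == d.p + 3) return st.a2;
    if (j == d.p + 4) return st.logsigma;
    if (j == d.p + 5) return st.logk;
    return st.loglam;
  };

  for (int it = 0; it < niter; ++it) {
    // -- theta updates: block RW for beta and gamma, scalar RW otherwise --
    for (int j = 0; j < nblk; ++j) {
      vec old_beta = st.beta, old_gamma = st.gamma;
      double old_a1 = st.a1, old_a2 = st.a2, old_ls = st.logsigma,
             old_lk = st.logk, old_ll_ = st.loglam;
      double old_lp = cur_ll + theta_logprior(d, st);
      if (j == 0) {
        vec z(d.p);
        for (int r = 0; r < d.p; ++r) z(r) = R::rnorm(0.0, 1.0);
        st.beta += step(0) * (Lbeta * z);
      } else if (j == 1) {
        vec z(2);
        z(0) = R::rnorm(0.0, 1.0); z(1) = R::rnorm(0.0, 1.0);
        st.gamma += step(1) * (Lgamma * z);
      } else if (j == 2) st.a1 += R::rnorm(0.0, step(2));
      else if (j == 3) st.a2 += R::rnorm(0.0, step(3));
      else if (j == 4) st.logsigma += R::rnorm(0.0, step(4));
      else if (j == 5) st.logk += R::rnorm(0.0, step(5));
      else st.loglam += R::rnorm(0.0, step(6));
      vec new_pll;
      double new_ll = data_ll_total(d, st, new_pll);
      double new_lp = new_ll + theta_logprior(d, st);
      try_theta(j)++;
      if (std::log(R::runif(0.0, 1.0)) < new_lp - old_lp) {
        cur_ll = new_ll;
        cur_pll = new_pll;
        acc_theta(j)++;
      } else {
        st.beta = old_beta; st.gamma = old_gamma;
        st.a1 = old_a1; st.a2 = old_a2; st.logsigma = old_ls;
        st.logk = old_lk; st.loglam = old_ll_;
      }
    }

    // -- b updates --
    for (int i = 0; i < d.n; ++i) {
      rowvec old = st.b.row(i);
      vec z(d.q);
      for (int jq = 0; jq < d.q; ++jq) z(jq) = R::rnorm(0.0, 1.0);
      rowvec prop = old + bstep(i) * (st.Ld * z).t();
      double old_prior = -0.5 * as_scalar(old * st.Dinv * old.t());
      st.b.row(i) = prop;
      double new_ll = data_ll_patient(d, st, i);
      double new_prior = -0.5 * as_scalar(prop * st.Dinv * prop.t());
      try_b(i)++;
      if (std::log(R::runif(0.0, 1.0)) <
          (new_ll + new_prior) - (cur_pll(i) + old_prior)) {
        cur_ll += new_ll - cur_pll(i);
        cur_pll(i) = new_ll;
        acc_b(i)++;
      } else st.b.row(i) = old;
    }

    // -- likelihood-invariant translation move (exact Gibbs) --
    // priors are Gaussian in the shared shift delta, so draw it directly
    {
      mat prec = d.n * st.Dinv + (Atr.t() * Atr) / (d.sd_beta * d.sd_beta);
      vec rhs = st.Dinv * sum(st.b, 0).t() -
        (Atr.t() * st.beta) / (d.sd_beta * d.sd_beta);
      mat Lp = chol(inv_sympd(prec), "lower");
      vec z(d.q);
      for (int jq = 0; jq < d.q; ++jq) z(jq) = R::rnorm(0.0, 1.0);
      vec delta = solve(prec, rhs, solve_opts::likely_sympd) + Lp * z;
      st.b.each_row() -= delta.t();
      st.beta += Atr * delta;
      double dll = data_ll_total(d, st, cur_pll);  // refresh caches
      cur_ll = dll;
    }

    // -- D Gibbs step (conjugate inverse-Wishart) --
    mat Sb = prior_S + st.b.t() * st.b;
    st.D = riwish(prior_df + d.n, Sb);
    st.Dinv = inv_sympd(st.D);
    st.Ld = chol(st.D, "lower");

    // -- adapt proposal scales during burn-in --
    if (it < nburn && (it + 1) % 50 == 0) {
      for (int j = 0; j < nblk; ++j) {
        // target 0.23 for the multivariate blocks, 0.44 for scalars
        double tgt = (j <= 1) ? 0.23 : 0.44;
        double rate = try_theta(j) ? double(acc_theta(j)) / try_theta(j) : tgt;
        step(j) *= std::exp(1.5 * (rate - tgt));
        acc_theta(j) = try_theta(j) = 0;
      }
      for (int i = 0; i < d.n; ++i) {
        double rate = try_b(i) ? double(acc_b(i)) / try_b(i) : 0.3;
        bstep(i) *= std::exp(1.5 * (rate - 0.3));
        acc_b(i) = try_b(i) = 0;
      }
    }

    if (it >= nburn && (it - nburn) % thin == 0 && keep < nkeep) {
      for (int j = 0; j < ntheta; ++j) out_theta(keep, j) = get_theta(j);
      out_D.slice(keep) = st.D;
      out_bmean.row(keep) = mean(st.b, 0);
      keep++;
    }
    if ((it + 1) % 500 == 0) Rcpp::checkUserInterrupt();
  }

  vec acc_rate_theta(nblk);
  for (int j = 0; j < nblk; ++j)
    acc_rate_theta(j) = try_theta(j) ? double(acc_theta(j)) / try_theta(j) : NA_REAL;

  return Rcpp::List::create(
    Rcpp::Named("theta") = out_theta,
    Rcpp::Named("D") = out_D,
    Rcpp::Named("bmean") = out_bmean,
    Rcpp::Named("acc_theta") = acc_rate_theta,
    Rcpp::Named("acc_b") = mean(conv_to<vec>::from(acc_b) /
                                clamp(conv_to<vec>::from(try_b), 1.0, 1e12)));
}
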