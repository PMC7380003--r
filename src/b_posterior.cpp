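// Subject-level random-effects posterior for the joint model:
//   log p(b | Y, T* > t, theta) = sum_i log t_nu((y_i - m(t_i))/sigma)/sigma
//                                 - Lambda(0 -> t | b) - 0.5 b' D^{-1} b + C
// with Lambda evaluated by fixed-node quadrature on precomputed designs.
// All design matrices are precomputed in R and passed in a flat list.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct BPostData {
  vec y, m0_obs;    // observations and fixed-part mean at obs times
  mat Z_obs;        // random design at obs times (n x q)
  double sigma, nu;
  vec qw, logh0_eta, m0_nod, m0v_nod;  // quadrature weights / offsets
  mat Z_nod, Zv_nod;                   // random designs (level, velocity)
  double a1, a2;
  mat Dinv;
  bool has_surv;
};

static BPostData unpack(const Rcpp::List& dat) {
  BPostData d;
  d.y = Rcpp::as<vec>(dat["y"]);
  d.m0_obs = Rcpp::as<vec>(dat["m0_obs"]);
  d.Z_obs = Rcpp::as<mat>(dat["Z_obs"]);
  d.sigma = Rcpp::as<double>(dat["sigma"]);
  d.nu = Rcpp::as<double>(dat["nu"]);
  d.qw = Rcpp::as<vec>(dat["qw"]);
  d.logh0_eta = Rcpp::as<vec>(dat["logh0_eta"]);
  d.m0_nod = Rcpp::as<vec>(dat["m0_nod"]);
  d.m0v_nod = Rcpp::as<vec>(dat["m0v_nod"]);
  d.Z_nod = Rcpp::as<mat>(dat["Z_nod"]);
  d.Zv_nod = Rcpp::as<mat>(dat["Zv_nod"]);
  d.a1 = Rcpp::as<double>(dat["a1"]);
  d.a2 = Rcpp::as<double>(dat["a2"]);
  d.Dinv = Rcpp::as<mat>(dat["Dinv"]);
  d.has_surv = d.qw.n_elem > 0;
  return d;
}

static double logtarget(const BPostData& d, const vec& b,
                        vec* grad = nullptr, mat* hess = nullptr) {
  const double s2nu = d.nu * d.sigma * d.sigma;
  double ll = 0.0;
  vec r;
  if (d.y.n_elem > 0) {
    r = d.y - d.m0_obs - d.Z_obs * b;
    ll += accu(-0.5 * (d.nu + 1.0) * log1p(square(r) / s2nu));
  }
  vec hv;
  if (d.has_surv) {
    vec eta = d.logh0_eta + d.a1 * (d.m0_nod + d.Z_nod * b) +
              d.a2 * (d.m0v_nod + d.Zv_nod * b);
    hv = d.qw % exp(eta);
    ll -= accu(hv);
  }
  ll -= 0.5 * as_scalar(b.t() * d.Dinv * b);

  if (grad) {
    grad->zeros(b.n_elem);
    if (d.y.n_elem > 0) {
      vec u = (d.nu + 1.0) * r / (s2nu + square(r));
      *grad += d.Z_obs.t() * u;
    }
    if (d.has_surv)
      *grad -= d.a1 * (d.Z_nod.t() * hv) + d.a2 * (d.Zv_nod.t() * hv);
    *grad -= d.Dinv * b;
  }
  if (hess) {
    hess->zeros(b.n_elem, b.n_elem);
    if (d.y.n_elem > 0) {
      vec du = (d.nu + 1.0) * (square(r) - s2nu) / square(s2nu + square(r));
      *hess += d.Z_obs.t() * diagmat(du) * d.Z_obs;
    }
    if (d.has_surv) {
      mat A = d.a1 * d.Z_nod + d.a2 * d.Zv_nod;
      *hess -= A.t() * diagmat(hv) * A;
    }
    *hess -= d.Dinv;
  }
  return ll;
}

// [[Rcpp::export(name = ".cpp_b_logtarget")]]
double cpp_b_logtarget(const arma::vec& b, const Rcpp::List& dat) {
  BPostData d = unpack(dat);
  return logtarget(d, b);
}

// Vectorized over draws: one matrix op per likelihood block.
// [[Rcpp::export(name = ".cpp_b_logtarget_mat")]]
arma::vec cpp_b_logtarget_mat(const arma::mat& B, const Rcpp::List& dat) {
  BPostData d = unpack(dat);
  const uword nd = B.n_rows;
  vec out(nd, fill::zeros);
  const double s2nu = d.nu * d.sigma * d.sigma;
  if (d.y.n_elem > 0) {
    mat R = repmat(d.y - d.m0_obs, 1, nd) - d.Z_obs * B.t();  // n x nd
    out += (-0.5 * (d.nu + 1.0)) *
      sum(log1p(square(R) / s2nu), 0).t();
  }
  if (d.has_surv) {
    mat E = exp(repmat(d.logh0_eta + d.a1 * d.m0_nod + d.a2 * d.m0v_nod,
                       1, nd) +
                (d.a1 * d.Z_nod + d.a2 * d.Zv_nod) * B.t());
    out -= (d.qw.t() * E).t();
  }
  out -= 0.5 * sum((B * d.Dinv) % B, 1);
  return out;
}

// Damped Newton ascent with ridge fallback; returns mode, Hessian at mode,
// the attained log target and a convergence flag.
// [[Rcpp::export(name = ".cpp_b_mode")]]
Rcpp::List cpp_b_mode(const arma::vec& b0, const Rcpp::List& dat,
                      const int maxit = 100, const double tol = 1e-9) {
  BPostData d = unpack(dat);
  vec b = b0, g;
  mat H;
  double f = logtarget(d, b, &g, &H);
  bool conv = false;
  for (int it = 0; it < maxit; ++it) {
    mat Hn = -H;
    double ridge = 0.0;
    mat L;
    while (!chol(L, Hn + ridge * eye(b.n_elem, b.n_elem))) {
      ridge = (ridge == 0.0) ? 1e-6 : ridge * 10.0;
      if (ridge > 1e8) Rcpp::stop("Hessian irreparably indefinite");
    }
    Hn += ridge * eye(b.n_elem, b.n_elem);
    vec step = solve(Hn, g, solve_opts::likely_sympd);
    double alpha = 1.0, fnew = -datum::inf;
    vec bnew;
    for (int ls = 0; ls < 30; ++ls) {
      bnew = b + alpha * step;
      fnew = logtarget(d, bnew);
      if (std::isfinite(fnew) && fnew >= f - 1e-12) break;
      alpha *= 0.5;
    }
    double delta = fnew - f;
    b = bnew;
    f = logtarget(d, b, &g, &H);
    if (std::abs(delta) < tol && norm(g, 2) < 1e-6) { conv = true; break; }
  }
  return Rcpp::List::create(Rcpp::Named("mode") = b,
                            Rcpp::Named("hessian") = H,
                            Rcpp::Named("logpost") = f,
                            Rcpp::Named("converged") = conv);
}
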