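// Fast kernels for the schedule-evaluation engine: cumulative-hazard curves
// over the posterior draws and monotone inversion of the dynamic survival
// curve with per-draw linear interpolation of the cumulative hazard.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Cumulative hazard at every panel edge for each draw.
// base: log-hazard offset per node; Ag: node x q association design;
// B: ndraw x q draws; wts: node quadrature weights; seg: 1-based panel
// index per node (non-decreasing); nseg: number of panels.
// Returns ndraw x (nseg + 1), first column zero.
// [[Rcpp::export(name = ".cpp_cum_lam")]]
arma::mat cpp_cum_lam(const arma::vec& base, const arma::mat& Ag,
                      const arma::mat& B, const arma::vec& wts,
                      const arma::ivec& seg, const int nseg) {
  const uword nn = base.n_elem, nd = B.n_rows;
  mat M = Ag * B.t();              // node x ndraw
  mat out(nd, nseg + 1, fill::zeros);
  for (uword j = 0; j < nd; ++j) {
    double acc = 0.0;
    int cur = 1;
    for (uword i = 0; i < nn; ++i) {
      int s = seg(i);
      if (s != cur) {
        for (int k = cur; k < s; ++k) out(j, k) = acc;
        cur = s;
      }
      acc += wts(i) * std::exp(base(i) + M(i, j));
    }
    for (int k = cur; k <= nseg; ++k) out(j, k) = acc;
  }
  return out;
}

static double pi_at(const mat& Lam, const vec& edges, const vec& w,
                    const vec& Lam_t, double u) {
  const uword nseg = edges.n_elem - 1;
  uword k = 0;
  while (k < nseg - 1 && edges(k + 1) < u) ++k;
  double fr = (u - edges(k)) / (edges(k + 1) - edges(k));
  if (fr < 0) fr = 0;
  if (fr > 1) fr = 1;
  double num = 0.0;
  for (uword j = 0; j < Lam.n_rows; ++j) {
    double L = Lam(j, k) + fr * (Lam(j, k + 1) - Lam(j, k)) - Lam_t(j);
    if (L < 0) L = 0;
    num += w(j) * std::exp(-L);
  }
  return num;
}

// Survival probabilities pi(u | t) for a vector of times.
// [[Rcpp::export(name = ".cpp_pi_at")]]
arma::vec cpp_pi_at(const arma::mat& Lam, const arma::vec& edges,
                    const arma::vec& w, const arma::vec& Lam_t,
                    const double t, const arma::vec& u) {
  vec out(u.n_elem);
  for (uword i = 0; i < u.n_elem; ++i)
    out(i) = (u(i) <= t) ? 1.0 : pi_at(Lam, edges, w, Lam_t, u(i));
  return out;
}

// Monotone bisection for pi(u) = target on [lo, hi].
// [[Rcpp::export(name = ".cpp_curve_invert")]]
double cpp_curve_invert(const arma::mat& Lam, const arma::vec& edges,
                        const arma::vec& w, const arma::vec& Lam_t,
                        double lo, double hi, const double target,
                        const double tol) {
  while (hi - lo > tol) {
    double mid = 0.5 * (lo + hi);
    if (pi_at(Lam, edges, w, Lam_t, mid) > target) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}
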