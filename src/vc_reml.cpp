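// REML profile likelihood for the variance-component QTL models.
//
// V = s2e * W with W = ga * G + gq * Z + I, where G (polygenic
// relationship) and Z (locus IBD) are block diagonal over families; the
// residual variance is profiled out, so the objective is a function of the
// log variance ratios only. Evaluating per block keeps the cost linear in
// the number of families, and the optimizer runs entirely in C++ so a
// whole-genome scan converts the blocks just once per marker.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Block {
  arma::vec y;
  arma::mat X;
  arma::mat G;
  arma::mat Z;
  bool has_z;
};

struct Problem {
  std::vector<Block> blocks;
  int n = 0, p = 0;
};

Problem unpack(List blocks, bool has_z) {
  Problem pr;
  for (int b = 0; b < blocks.size(); ++b) {
    List blk = blocks[b];
    Block bb;
    bb.y = as<arma::vec>(blk["y"]);
    bb.X = as<arma::mat>(blk["X"]);
    bb.G = as<arma::mat>(blk["G"]);
    bb.has_z = has_z;
    if (has_z) bb.Z = as<arma::mat>(blk["Z"]);
    pr.n += bb.y.n_elem;
    pr.p = bb.X.n_cols;
    pr.blocks.push_back(std::move(bb));
  }
  return pr;
}

// negative REML log-likelihood with the residual variance profiled out;
// optionally returns the profiled estimates
double reml_nll(const Problem& pr, double ga, double gq,
                arma::vec* beta_out = nullptr, double* s2e_out = nullptr) {
  const int p = pr.p;
  arma::mat XtWiX(p, p, arma::fill::zeros);
  arma::vec XtWiy(p, arma::fill::zeros);
  double yty = 0.0, logdetW = 0.0;
  for (const Block& bb : pr.blocks) {
    const int nb = bb.y.n_elem;
    arma::mat W = ga * bb.G + arma::eye(nb, nb);
    if (bb.has_z) W += gq * bb.Z;
    arma::mat L;
    if (!arma::chol(L, W, "lower")) return R_PosInf;
    arma::mat Xs = arma::solve(arma::trimatl(L), bb.X);
    arma::vec ys = arma::solve(arma::trimatl(L), bb.y);
    XtWiX += Xs.t() * Xs;
    XtWiy += Xs.t() * ys;
    yty += arma::dot(ys, ys);
    logdetW += 2.0 * arma::sum(arma::log(L.diag()));
  }
  arma::vec beta;
  if (!arma::solve(beta, XtWiX, XtWiy)) return R_PosInf;
  const double rss = yty - arma::dot(XtWiy, beta);
  const int nmp = pr.n - p;
  if (rss <= 0.0 || nmp <= 0) return R_PosInf;
  const double s2e = rss / nmp;
  double ldx, sign;
  arma::log_det(ldx, sign, XtWiX);
  if (sign <= 0.0) return R_PosInf;
  if (beta_out) *beta_out = beta;
  if (s2e_out) *s2e_out = s2e;
  return 0.5 * (nmp * std::log(s2e) + logdetW + ldx +
                nmp * (1.0 + std::log(2.0 * M_PI)));
}

double clamp(double x, double lo, double hi) {
  return std::min(std::max(x, lo), hi);
}

// golden-section minimization of the 1-parameter (no-QTL) profile
double golden(const Problem& pr, double lo, double hi) {
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  double a = lo, b = hi;
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = reml_nll(pr, std::exp(c), 0.0);
  double fd = reml_nll(pr, std::exp(d), 0.0);
  for (int it = 0; it < 120 && (b - a) > 1e-7; ++it) {
    if (fc < fd) {
      b = d; d = c; fd = fc;
      c = b - gr * (b - a);
      fc = reml_nll(pr, std::exp(c), 0.0);
    } else {
      a = c; c = d; fc = fd;
      d = a + gr * (b - a);
      fd = reml_nll(pr, std::exp(d), 0.0);
    }
  }
  return (fc < fd) ? c : d;
}

// Nelder-Mead on the two log variance ratios, box-clamped
void nelder_mead(const Problem& pr, double lo, double hi,
                 arma::vec& par, double& fval) {
  auto f = [&](arma::vec v) {
    v[0] = clamp(v[0], lo, hi);
    v[1] = clamp(v[1], lo, hi);
    return reml_nll(pr, std::exp(v[0]), std::exp(v[1]));
  };
  std::vector<arma::vec> s(3);
  std::vector<double> fs(3);
  s[0] = par;
  s[1] = par + arma::vec({1.0, 0.0});
  s[2] = par + arma::vec({0.0, 1.0});
  for (int i = 0; i < 3; ++i) fs[i] = f(s[i]);
  for (int it = 0; it < 300; ++it) {
    // order
    std::vector<int> idx = {0, 1, 2};
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return fs[a] < fs[b]; });
    std::vector<arma::vec> s2 = {s[idx[0]], s[idx[1]], s[idx[2]]};
    std::vector<double> f2 = {fs[idx[0]], fs[idx[1]], fs[idx[2]]};
    s = s2; fs = f2;
    // f-spread alone suffices: on the clamped boundary plateau the simplex
    // can stay wide while the objective is already flat
    if (std::abs(fs[2] - fs[0]) < 1e-8 ||
        arma::norm(s[2] - s[0]) < 1e-5) break;
    arma::vec cen = (s[0] + s[1]) / 2.0;
    arma::vec xr = cen + (cen - s[2]);
    double fr = f(xr);
    if (fr < fs[0]) {
      arma::vec xe = cen + 2.0 * (cen - s[2]);
      double fe = f(xe);
      if (fe < fr) { s[2] = xe; fs[2] = fe; }
      else { s[2] = xr; fs[2] = fr; }
    } else if (fr < fs[1]) {
      s[2] = xr; fs[2] = fr;
    } else {
      arma::vec xc = cen + 0.5 * (s[2] - cen);
      double fc = f(xc);
      if (fc < fs[2]) { s[2] = xc; fs[2] = fc; }
      else {
        s[1] = s[0] + 0.5 * (s[1] - s[0]); fs[1] = f(s[1]);
        s[2] = s[0] + 0.5 * (s[2] - s[0]); fs[2] = f(s[2]);
      }
    }
  }
  int best = (fs[0] <= fs[1] && fs[0] <= fs[2]) ? 0 : (fs[1] <= fs[2] ? 1 : 2);
  par = s[best];
  par[0] = clamp(par[0], lo, hi);
  par[1] = clamp(par[1], lo, hi);
  fval = fs[best];
}

List report(const Problem& pr, const arma::vec& par, bool has_z) {
  const double ga = std::exp(par[0]);
  const double gq = has_z ? std::exp(par[1]) : 0.0;
  arma::vec beta;
  double s2e = NA_REAL;
  const double nll = reml_nll(pr, ga, gq, &beta, &s2e);
  return List::create(_["nll"] = nll, _["loglik"] = -nll,
                      _["par"] = NumericVector(par.begin(), par.end()),
                      _["beta"] = beta, _["s2e"] = s2e,
                      _["s2a"] = ga * s2e, _["s2q"] = gq * s2e);
}

}  // namespace

// single evaluation of the profiled negative REML log-likelihood; used by
// the profile-grid checks
// [[Rcpp::export(name = ".vc_reml_eval")]]
List vc_reml_eval(NumericVector par, List blocks, bool has_z) {
  Problem pr = unpack(blocks, has_z);
  arma::vec p(par.begin(), par.size());
  return report(pr, p, has_z);
}

// full REML fit: golden section (no QTL) or multi-start Nelder-Mead (QTL)
// over the log variance ratios within [lower, upper]
// [[Rcpp::export(name = ".vc_reml_fit")]]
List vc_reml_fit(List blocks, bool has_z, NumericMatrix starts,
                 double lower, double upper) {
  Problem pr = unpack(blocks, has_z);
  if (!has_z) {
    arma::vec par(1);
    par[0] = golden(pr, lower, upper);
    return report(pr, par, false);
  }
  arma::vec best;
  double best_f = R_PosInf;
  for (int s = 0; s < starts.nrow(); ++s) {
    arma::vec par = {starts(s, 0), starts(s, 1)};
    double fval;
    nelder_mead(pr, lower, upper, par, fval);
    if (fval < best_f) { best_f = fval; best = par; }
  }
  return report(pr, best, true);
}
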