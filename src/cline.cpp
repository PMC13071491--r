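#include <Rcpp.h>
using namespace Rcpp;

// Szymura-Barton cline shape. The core is a logistic in x scaled so that the
// maximum slope at the centre is (pmax - pmin) / w. Stepped variants replace
// the sigmoid beyond the tail junctions c - deltaL / c + deltaR with
// exponential tails whose slope is a fraction tau of the junction slope;
// both tail forms are continuous with the core at the junction.
static inline double cline_g(const double x, const double c, const double w,
                             const double dL, const double tL,
                             const double dR, const double tR,
                             const bool tails) {
  if (tails) {
    if (x <= c - dL) {
      const double eL = std::exp(4.0 * dL / w);
      return (1.0 / (1.0 + eL)) *
             std::exp((4.0 * tL * (x - c + dL) / w) / (1.0 + 1.0 / eL));
    }
    if (x >= c + dR) {
      const double eR = std::exp(4.0 * dR / w);
      return 1.0 - (1.0 / (1.0 + eR)) *
             std::exp((-4.0 * tR * (x - c - dR) / w) / (1.0 + 1.0 / eR));
    }
  }
  return 1.0 / (1.0 + std::exp(-4.0 * (x - c) / w));
}

// [[Rcpp::export]]
NumericVector cline_pred_cpp(NumericVector x, double c, double w,
                             double pmin, double pmax,
                             double dL, double tL, double dR, double tR,
                             bool tails) {
  const int m = x.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    out[i] = pmin + (pmax - pmin) * cline_g(x[i], c, w, dL, tL, dR, tR, tails);
  }
  return out;
}

// Negative binomial-sampling log-likelihood of per-population allele counts
// under the cline, without the lchoose(n, k) constant (added once in R).
// Predicted frequencies are clamped to [eps, 1 - eps].
// [[Rcpp::export]]
double cline_negll_binom_cpp(NumericVector x, NumericVector k, NumericVector n,
                             double c, double w, double pmin, double pmax,
                             double dL, double tL, double dR, double tR,
                             bool tails, double eps) {
  const int m = x.size();
  double nll = 0.0;
  for (int i = 0; i < m; ++i) {
    double p = pmin + (pmax - pmin) * cline_g(x[i], c, w, dL, tL, dR, tR, tails);
    if (p < eps) p = eps;
    if (p > 1.0 - eps) p = 1.0 - eps;
    nll -= k[i] * std::log(p) + (n[i] - k[i]) * std::log1p(-p);
  }
  return nll;
}

static double negll_binom_full(const NumericVector& x, const NumericVector& k,
                               const NumericVector& n, const double* f,
                               const bool tails, const double eps) {
  const int m = x.size();
  double nll = 0.0;
  for (int i = 0; i < m; ++i) {
    double p = f[2] + (f[3] - f[2]) *
      cline_g(x[i], f[0], f[1], f[4], f[5], f[6], f[7], tails);
    if (p < eps) p = eps;
    if (p > 1.0 - eps) p = 1.0 - eps;
    nll -= k[i] * std::log(p) + (n[i] - k[i]) * std::log1p(-p);
  }
  return nll;
}

// Central-difference gradient of the binomial negative log-likelihood with
// respect to the free parameters (0-based indices into the full 8-vector
// centre, width, pmin, pmax, deltaL, tauL, deltaR, tauR). Doing the
// differencing here keeps the optimizer's per-iteration R overhead at two
// calls regardless of model dimension.
// [[Rcpp::export]]
NumericVector cline_negll_binom_grad_cpp(NumericVector x, NumericVector k,
                                         NumericVector n, NumericVector full,
                                         IntegerVector free_idx,
                                         NumericVector step,
                                         bool tails, double eps) {
  const int d = free_idx.size();
  NumericVector grad(d);
  std::vector<double> f(full.begin(), full.end());
  for (int j = 0; j < d; ++j) {
    const int idx = free_idx[j];
    const double v = f[idx];
    const double h = step[j];
    f[idx] = v + h;
    const double up = negll_binom_full(x, k, n, f.data(), tails, eps);
    f[idx] = v - h;
    const double dn = negll_binom_full(x, k, n, f.data(), tails, eps);
    f[idx] = v;
    grad[j] = (up - dn) / (2.0 * h);
  }
  return grad;
}

static double negll_gauss_full(const NumericVector& x, const NumericVector& y,
                               const double* f, const bool tails,
                               const double sigma_floor) {
  const int m = x.size();
  double ss = 0.0;
  for (int i = 0; i < m; ++i) {
    const double p = f[2] + (f[3] - f[2]) *
      cline_g(x[i], f[0], f[1], f[4], f[5], f[6], f[7], tails);
    const double r = y[i] - p;
    ss += r * r;
  }
  double s2 = ss / m;
  const double fl2 = sigma_floor * sigma_floor;
  if (s2 < fl2) s2 = fl2;
  return 0.5 * m * (std::log(2.0 * M_PI * s2)) + 0.5 * ss / s2;
}

// [[Rcpp::export]]
NumericVector cline_negll_gauss_grad_cpp(NumericVector x, NumericVector y,
                                         NumericVector full,
                                         IntegerVector free_idx,
                                         NumericVector step,
                                         bool tails, double sigma_floor) {
  const int d = free_idx.size();
  NumericVector grad(d);
  std::vector<double> f(full.begin(), full.end());
  for (int j = 0; j < d; ++j) {
    const int idx = free_idx[j];
    const double v = f[idx];
    const double h = step[j];
    f[idx] = v + h;
    const double up = negll_gauss_full(x, y, f.data(), tails, sigma_floor);
    f[idx] = v - h;
    const double dn = negll_gauss_full(x, y, f.data(), tails, sigma_floor);
    f[idx] = v;
    grad[j] = (up - dn) / (2.0 * h);
  }
  return grad;
}

// Gaussian negative log-likelihood with the noise scale sigma profiled out by
// its MLE, floored at sigma_floor. Used for environmental (continuous)
// responses on the [0, 1] scale.
// [[Rcpp::export]]
double cline_negll_gauss_cpp(NumericVector x, NumericVector y,
                             double c, double w, double pmin, double pmax,
                             double dL, double tL, double dR, double tR,
                             bool tails, double sigma_floor) {
  const int m = x.size();
  double ss = 0.0;
  for (int i = 0; i < m; ++i) {
    const double p = pmin + (pmax - pmin) *
      cline_g(x[i], c, w, dL, tL, dR, tR, tails);
    const double r = y[i] - p;
    ss += r * r;
  }
  double s2 = ss / m;
  const double fl2 = sigma_floor * sigma_floor;
  if (s2 < fl2) s2 = fl2;
  // -sum log N(y | p, s2) at the profiled (floored) sigma
  return 0.5 * m * (std::log(2.0 * M_PI * s2)) + 0.5 * ss / s2;
}
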