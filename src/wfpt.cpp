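#include <Rcpp.h>
#include <cmath>
#include "wfpt.h"

using namespace Rcpp;

// First-passage-time density of a Wiener diffusion (unit diffusion
// coefficient) at the LOWER of two absorbing boundaries {0, a}, started at
// relative position w = z/a, with drift v, evaluated at decision time t.
//
// The density factorizes as
//   f(t | v, a, w) = a^{-2} exp(-v a w - v^2 t / 2) * f0(t / a^2, w)
// where f0 is the zero-drift unit-boundary density.  f0 has two series
// representations; term counts follow the usual absolute-error bounds and
// the cheaper series is used at each t.

static const double LOG_2PI = 1.8378770664093454836;

// number of terms for the small-time series, absolute error eps on f0
static inline double ks_terms(double u, double eps) {
  if (2.0 * std::sqrt(2.0 * M_PI * u) * eps < 1.0) {
    double k = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * u)));
    return std::max(k, std::sqrt(u) + 1.0);
  }
  return 2.0;
}

// number of terms for the large-time series
static inline double kl_terms(double u, double eps) {
  if (M_PI * u * eps < 1.0) {
    double k = std::sqrt(-2.0 * std::log(M_PI * u * eps) / (M_PI * M_PI * u));
    return std::max(k, 1.0 / (M_PI * std::sqrt(u)));
  }
  return 1.0 / (M_PI * std::sqrt(u));
}

// zero-drift, unit-boundary density at scaled time u, start w
static double f0_density(double u, double w, double eps) {
  double ks = ks_terms(u, eps);
  double kl = kl_terms(u, eps);
  double f = 0.0;
  if (ks < kl) {
    int K = (int)std::ceil(ks);
    for (int k = -K; k <= K; ++k) {
      double x = w + 2.0 * k;
      f += x * std::exp(-x * x / (2.0 * u));
    }
    f /= std::sqrt(2.0 * M_PI * u * u * u);
  } else {
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      f += k * std::exp(-k * k * M_PI * M_PI * u / 2.0) * std::sin(k * M_PI * w);
    }
    f *= M_PI;
  }
  return std::max(f, 0.0);
}

// log density of first passage at the lower boundary; -Inf when <= 0
double wfpt_logpdf1(double t, double v, double a, double w, double eps) {
  if (!(t > 0.0)) return R_NegInf;
  double u = t / (a * a);
  double f0 = f0_density(u, w, eps);
  if (f0 <= 0.0) return R_NegInf;
  return -2.0 * std::log(a) - v * a * w - v * v * t / 2.0 + std::log(f0);
}

// [[Rcpp::export]]
NumericVector wfpt_logpdf_cpp(NumericVector t, double v, double a, double w,
                              bool upper, double eps) {
  // upper boundary via reflection: (v, w) -> (-v, 1 - w)
  double vv = upper ? -v : v;
  double ww = upper ? 1.0 - w : w;
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = wfpt_logpdf1(t[i], vv, a, ww, eps);
  return out;
}

// Euler-Maruyama simulation of the diffusion; used as an independent check
// on the series density and the inverse-CDF sampler.  Returns decision
// times and which boundary was absorbed (1 = upper).
// [[Rcpp::export]]
List euler_fpt_cpp(int n, double v, double a, double w, double dt,
                   double tmax) {
  NumericVector times(n);
  IntegerVector hit_upper(n);
  double sd = std::sqrt(dt);
  int nmax = (int)std::ceil(tmax / dt);
  for (int i = 0; i < n; ++i) {
    double x = w * a;
    int step = 0;
    while (step < nmax) {
      x += v * dt + sd * norm_rand();
      ++step;
      if (x >= a) { hit_upper[i] = 1; break; }
      if (x <= 0.0) { hit_upper[i] = 0; break; }
    }
    times[i] = step * dt;
    if (step >= nmax && x < a && x > 0.0) times[i] = NA_REAL;
  }
  return List::create(Named("t") = times, Named("upper") = hit_upper);
}
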