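#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Chebyshev distance between m-length templates, early exit above r
static inline double cheb_capped(const double* x, int i, int j, int m, double r) {
  double d = 0.0;
  for (int k = 0; k < m; ++k) {
    double a = std::fabs(x[i + k] - x[j + k]);
    if (a > d) {
      d = a;
      if (d > r) return d;
    }
  }
  return d;
}

// Approximate entropy: phi(m) - phi(m+1), template matches d <= r,
// self-matches included (classic definition). Symmetric pair counting with
// a shared m / m+1 pass.
// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(NumericVector xv, int m, double r) {
  int n = xv.size();
  const double* x = xv.begin();
  int ntm = n - m + 1;       // templates of length m
  int ntm1 = n - m;          // templates of length m+1
  if (ntm1 < 1) return NA_REAL;
  std::vector<int> cm(ntm, 1), cm1(ntm1, 1);  // self-matches
  for (int i = 0; i < ntm - 1; ++i) {
    for (int j = i + 1; j < ntm; ++j) {
      double d = cheb_capped(x, i, j, m, r);
      if (d <= r) {
        ++cm[i]; ++cm[j];
        if (j < ntm1) {  // i < j so i < ntm1 too
          double a = std::fabs(x[i + m] - x[j + m]);
          if (a <= r) { ++cm1[i]; ++cm1[j]; }
        }
      }
    }
  }
  double phim = 0.0, phim1 = 0.0;
  for (int i = 0; i < ntm; ++i) phim += std::log((double)cm[i] / ntm);
  for (int i = 0; i < ntm1; ++i) phim1 += std::log((double)cm1[i] / ntm1);
  return phim / ntm - phim1 / ntm1;
}

// Sample entropy: -log(A/B); B = m-template match pairs (i < j), A =
// (m+1)-template match pairs, both over the first n - m template starts,
// self-matches excluded (Richman-Moorman).
// [[Rcpp::export(name = ".sampen_cpp")]]
double sampen_cpp(NumericVector xv, int m, double r) {
  int n = xv.size();
  const double* x = xv.begin();
  int nt = n - m;
  if (nt < 2) return NA_REAL;
  long long A = 0, B = 0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      if (cheb_capped(x, i, j, m, r) <= r) {
        ++B;
        if (std::fabs(x[i + m] - x[j + m]) <= r) ++A;
      }
    }
  }
  if (B == 0 || A == 0) return 0.0;  // degenerate convention: no information
  return -std::log((double)A / (double)B);
}

// Fuzzy entropy with exponential membership exp(-(d/r)^2), Chebyshev d,
// self-matches excluded: ln phi(m) - ln phi(m+1), both phis over a common
// set of n - m template starts so the two are comparable.
// [[Rcpp::export(name = ".fuzzyen_cpp")]]
double fuzzyen_cpp(NumericVector xv, int m, double r) {
  int n = xv.size();
  const double* x = xv.begin();
  int nt = n - m;
  if (nt < 2) return NA_REAL;
  double accm = 0.0, accm1 = 0.0;
  double inv_r2 = 1.0 / (r * r);
  double cutoff = 6.1 * r;  // exp(-(d/r)^2) below double epsilon past here
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(x[i + k] - x[j + k]);
        if (a > d) d = a;
      }
      if (d > cutoff) continue;  // both memberships vanish (d1 >= d)
      accm += std::exp(-d * d * inv_r2);
      double a = std::fabs(x[i + m] - x[j + m]);
      double d1 = a > d ? a : d;
      if (d1 <= cutoff) accm1 += std::exp(-d1 * d1 * inv_r2);
    }
  }
  double npairs = 0.5 * (double)nt * (nt - 1);
  double phim = accm / npairs, phim1 = accm1 / npairs;
  if (phim <= 0 || phim1 <= 0) return 0.0;
  return std::log(phim) - std::log(phim1);
}
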