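#include <Rcpp.h>
using namespace Rcpp;

// Natural cubic spline through (xs, ys), evaluated at integer grid 0..n-1.
// Used for the upper/lower extrema envelopes inside the sifting loop.
static void spline_eval(const std::vector<int>& xs, const std::vector<double>& ys,
                        int n, std::vector<double>& out) {
  int k = xs.size();
  if (k == 1) {
    std::fill(out.begin(), out.end(), ys[0]);
    return;
  }
  if (k == 2) {
    double slope = (ys[1] - ys[0]) / (double)(xs[1] - xs[0]);
    for (int t = 0; t < n; ++t) out[t] = ys[0] + slope * (t - xs[0]);
    return;
  }
  // second derivatives (natural boundary), tridiagonal solve
  std::vector<double> h(k - 1), alpha(k, 0.0), l(k), mu(k), z(k), m2(k);
  for (int i = 0; i < k - 1; ++i) h[i] = (double)(xs[i + 1] - xs[i]);
  for (int i = 1; i < k - 1; ++i)
    alpha[i] = 3.0 * ((ys[i + 1] - ys[i]) / h[i] - (ys[i] - ys[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < k - 1; ++i) {
    l[i] = 2.0 * (xs[i + 1] - xs[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  l[k - 1] = 1.0; z[k - 1] = 0.0; m2[k - 1] = 0.0;
  for (int i = k - 2; i >= 0; --i) m2[i] = z[i] - mu[i] * m2[i + 1];

  int seg = 0;
  for (int t = 0; t < n; ++t) {
    while (seg < k - 2 && t > xs[seg + 1]) ++seg;
    double dx = (double)(t - xs[seg]);
    double hs = h[seg];
    double a = ys[seg];
    double b = (ys[seg + 1] - ys[seg]) / hs - hs * (2.0 * m2[seg] + m2[seg + 1]) / 6.0;
    double c = m2[seg] / 2.0;
    double d = (m2[seg + 1] - m2[seg]) / (6.0 * hs);
    out[t] = a + b * dx + c * dx * dx + d * dx * dx * dx;
  }
}

// strict local extrema (sign change of first difference); flat runs give none
static void find_extrema(const std::vector<double>& x, std::vector<int>& mx,
                         std::vector<int>& mn) {
  mx.clear(); mn.clear();
  int n = x.size();
  for (int i = 1; i < n - 1; ++i) {
    double dl = x[i] - x[i - 1], dr = x[i + 1] - x[i];
    if (dl > 0 && dr < 0) mx.push_back(i);
    else if (dl < 0 && dr > 0) mn.push_back(i);
  }
}

// Empirical mode decomposition by sifting. Envelope knots are the interior
// extrema plus both endpoints (clamped-to-signal ends), a standard boundary
// treatment. Cauchy-type stopping criterion with tolerance `tol`.
// [[Rcpp::export(name = ".emd_cpp")]]
List emd_cpp(NumericVector signal, int max_imf = 10, double tol = 0.2,
             int max_sift = 50) {
  int n = signal.size();
  std::vector<double> r(signal.begin(), signal.end());
  std::vector<double> h(n), hnew(n), upper(n), lower(n);
  std::vector<int> mx, mn;
  std::vector<std::vector<double> > imfs;

  for (int k = 0; k < max_imf; ++k) {
    find_extrema(r, mx, mn);
    if ((int)mx.size() < 2 || (int)mn.size() < 2) break;
    h = r;
    for (int s = 0; s < max_sift; ++s) {
      find_extrema(h, mx, mn);
      if ((int)mx.size() < 2 || (int)mn.size() < 2) break;
      // mirror the two outermost extrema about each boundary so the spline
      // envelopes are anchored outside the signal (standard edge treatment)
      std::vector<int> ux, lx; std::vector<double> uy, ly;
      ux.push_back(-mx[1]); uy.push_back(h[mx[1]]);
      ux.push_back(-mx[0]); uy.push_back(h[mx[0]]);
      for (size_t i = 0; i < mx.size(); ++i) { ux.push_back(mx[i]); uy.push_back(h[mx[i]]); }
      int e = n - 1;
      ux.push_back(2 * e - mx[mx.size() - 1]); uy.push_back(h[mx[mx.size() - 1]]);
      ux.push_back(2 * e - mx[mx.size() - 2]); uy.push_back(h[mx[mx.size() - 2]]);
      lx.push_back(-mn[1]); ly.push_back(h[mn[1]]);
      lx.push_back(-mn[0]); ly.push_back(h[mn[0]]);
      for (size_t i = 0; i < mn.size(); ++i) { lx.push_back(mn[i]); ly.push_back(h[mn[i]]); }
      lx.push_back(2 * e - mn[mn.size() - 1]); ly.push_back(h[mn[mn.size() - 1]]);
      lx.push_back(2 * e - mn[mn.size() - 2]); ly.push_back(h[mn[mn.size() - 2]]);
      spline_eval(ux, uy, n, upper);
      spline_eval(lx, ly, n, lower);
      double num = 0.0, den = 0.0;
      for (int t = 0; t < n; ++t) {
        double m = 0.5 * (upper[t] + lower[t]);
        hnew[t] = h[t] - m;
        num += m * m;
        den += h[t] * h[t];
      }
      h = hnew;
      if (den <= 0.0 || num / den < tol) break;
    }
    imfs.push_back(h);
    for (int t = 0; t < n; ++t) r[t] -= h[t];
  }

  int k = imfs.size();
  NumericMatrix M(n, k > 0 ? k : 0);
  for (int j = 0; j < k; ++j)
    for (int t = 0; t < n; ++t) M(t, j) = imfs[j][t];
  return List::create(_["imf"] = M, _["residual"] = NumericVector(r.begin(), r.end()));
}
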