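#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Centred rolling quantile with shrinking windows at the edges.
// Matches stats::quantile() type 7 so R-level oracles agree exactly.
static double quantile7(std::vector<double>& buf, double q) {
  const int m = buf.size();
  if (m == 1) return buf[0];
  double h = (m - 1) * q;
  int lo = (int)std::floor(h);
  double frac = h - lo;
  std::nth_element(buf.begin(), buf.begin() + lo, buf.end());
  double xlo = buf[lo];
  if (frac == 0.0) return xlo;
  std::nth_element(buf.begin() + lo + 1, buf.begin() + lo + 1, buf.end());
  double xhi = buf[lo + 1];
  return xlo + frac * (xhi - xlo);
}

// [[Rcpp::export]]
NumericVector roll_quantile_c(NumericVector x, int width, double q) {
  const int n = x.size();
  NumericVector out(n);
  const int h = width / 2;
  std::vector<double> buf;
  buf.reserve(width + 1);
  for (int i = 0; i < n; ++i) {
    int a = std::max(0, i - h);
    int b = std::min(n - 1, i + h);
    buf.assign(x.begin() + a, x.begin() + b + 1);
    out[i] = quantile7(buf, q);
  }
  return out;
}

// Per-window summary statistics over four channels (3 dynamic axes + VeDBA):
// mean, sd, min, max, skewness, excess kurtosis -> 24 features per window.
// Constant windows get skewness/kurtosis 0 by convention.
// [[Rcpp::export]]
NumericMatrix roll_features_c(NumericMatrix chan, int window, int stride) {
  const int n = chan.nrow(), k = chan.ncol();
  const int nw = (n < window) ? 0 : (n - window) / stride + 1;
  NumericMatrix out(nw, 6 * k);
  for (int w = 0; w < nw; ++w) {
    const int s = w * stride;
    for (int c = 0; c < k; ++c) {
      double m = 0.0, mn = chan(s, c), mx = chan(s, c);
      for (int j = 0; j < window; ++j) {
        double v = chan(s + j, c);
        m += v;
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
      m /= window;
      double m2 = 0.0, m3 = 0.0, m4 = 0.0;
      for (int j = 0; j < window; ++j) {
        double d = chan(s + j, c) - m;
        double d2 = d * d;
        m2 += d2; m3 += d2 * d; m4 += d2 * d2;
      }
      m2 /= window; m3 /= window; m4 /= window;
      double sd = std::sqrt(m2 * window / (window - 1.0));
      double skew = 0.0, kurt = 0.0;
      if (m2 > 1e-24) {
        skew = m3 / std::pow(m2, 1.5);
        kurt = m4 / (m2 * m2) - 3.0;
      }
      const int o = 6 * c;
      out(w, o + 0) = m;
      out(w, o + 1) = sd;
      out(w, o + 2) = mn;
      out(w, o + 3) = mx;
      out(w, o + 4) = skew;
      out(w, o + 5) = kurt;
    }
  }
  return out;
}
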