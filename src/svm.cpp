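#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Two-class C-SVC with RBF kernel, solved by SMO with maximal-violating-pair
// working-set selection (the classic LIBSVM strategy without shrinking).
// Labels must be +1 / -1. Kernel rows are cached lazily with a hard cap so
// memory stays bounded on larger training sets.

struct RbfProblem {
  std::vector<double> Xr;  // row-major copy for cache-friendly kernel rows
  const NumericVector& y;
  double gamma;
  int n, d;
  std::vector<double> sqnorm;
  std::vector< std::vector<double> > cache;
  std::vector<int> cache_slot;
  std::vector<int> slot_owner;
  size_t max_rows;
  size_t next_evict;

  RbfProblem(const NumericMatrix& X_, const NumericVector& y_, double g,
             size_t max_rows_)
    : y(y_), gamma(g), n(X_.nrow()), d(X_.ncol()),
      cache_slot(n, -1), max_rows(max_rows_), next_evict(0) {
    // reserve so push_back never reallocates: row() hands out references
    // into `cache` that must survive a second row() call
    cache.reserve(max_rows);
    slot_owner.reserve(max_rows);
    Xr.resize((size_t)n * d);
    sqnorm.resize(n);
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < d; ++j) {
        double v = X_(i, j);
        Xr[(size_t)i * d + j] = v;
        s += v * v;
      }
      sqnorm[i] = s;
    }
  }

  double kval(int a, int b) const {
    const double* pa = &Xr[(size_t)a * d];
    const double* pb = &Xr[(size_t)b * d];
    double dot = 0.0;
    for (int j = 0; j < d; ++j) dot += pa[j] * pb[j];
    return std::exp(-gamma * (sqnorm[a] + sqnorm[b] - 2.0 * dot));
  }

  const std::vector<double>& row(int i) {
    if (cache_slot[i] >= 0) return cache[cache_slot[i]];
    int slot;
    if (cache.size() < max_rows) {
      slot = cache.size();
      cache.push_back(std::vector<double>(n));
      slot_owner.push_back(i);
    } else {
      slot = next_evict;
      next_evict = (next_evict + 1) % max_rows;
      cache_slot[slot_owner[slot]] = -1;
      slot_owner[slot] = i;
    }
    cache_slot[i] = slot;
    std::vector<double>& r = cache[slot];
    for (int t = 0; t < n; ++t) r[t] = kval(i, t);
    return r;
  }
};

// [[Rcpp::export]]
List svm_smo_fit_c(NumericMatrix X, NumericVector y, double cost, double gamma,
                   double eps = 1e-3, int max_iter = 200000,
                   int cache_rows = -1) {
  const int n = X.nrow();
  if (cache_rows <= 0) {
    // auto: cache the full kernel matrix up to ~500 MB
    double budget = 5e8 / (8.0 * n);
    cache_rows = (budget >= n) ? n : (int)budget;
  }
  RbfProblem prob(X, y, gamma, std::max(2, cache_rows));
  std::vector<double> alpha(n, 0.0), G(n, -1.0);

  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // first order: i maximises -y G over I_up; convergence check uses the
    // max violation against the minimum over I_low
    int i = -1;
    double gmax = -1e300, gmin = 1e300;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] > 0) ? (alpha[t] < cost) : (alpha[t] > 0);
      bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < cost);
      double v = -y[t] * G[t];
      if (up && v > gmax) { gmax = v; i = t; }
      if (low && v < gmin) gmin = v;
    }
    if (i < 0 || gmax - gmin < eps) break;

    // second order: j maximises the one-step objective decrease among
    // violating members of I_low (LIBSVM WSS2); K(t,t) = 1 for RBF.
    // Ki is copied: a later row(j) may evict the cache slot it lives in.
    std::vector<double> Ki = prob.row(i);
    int j = -1;
    double best = -1e300;
    for (int t = 0; t < n; ++t) {
      bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < cost);
      if (!low) continue;
      double v = -y[t] * G[t];
      if (v >= gmax) continue;
      double bdiff = gmax - v;
      double qc = 2.0 - 2.0 * y[i] * y[t] * Ki[t];
      if (qc <= 0) qc = 1e-12;
      double gain = bdiff * bdiff / qc;
      if (gain > best) { best = gain; j = t; }
    }
    if (j < 0) break;
    const std::vector<double>& Kj = prob.row(j);
    double ai_old = alpha[i], aj_old = alpha[j];

    // two-variable analytic solve with box clipping
    if (y[i] != y[j]) {
      double qc = Ki[i] + Kj[j] + 2.0 * Ki[j];
      if (qc <= 0) qc = 1e-12;
      double delta = (-G[i] - G[j]) / qc;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > cost) { alpha[i] = cost; alpha[j] = cost - diff; }
      } else {
        if (alpha[j] > cost) { alpha[j] = cost; alpha[i] = cost + diff; }
      }
    } else {
      double qc = Ki[i] + Kj[j] - 2.0 * Ki[j];
      if (qc <= 0) qc = 1e-12;
      double delta = (G[i] - G[j]) / qc;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > cost) {
        if (alpha[i] > cost) { alpha[i] = cost; alpha[j] = sum - cost; }
        if (alpha[j] > cost) { alpha[j] = cost; alpha[i] = sum - cost; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }
    double di = alpha[i] - ai_old, dj = alpha[j] - aj_old;
    if (std::fabs(di) < 1e-14 && std::fabs(dj) < 1e-14) break;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (di * y[i] * Ki[t] + dj * y[j] * Kj[t]);
  }

  // intercept from free support vectors, else midpoint of KKT bounds
  double bsum = 0.0; int bfree = 0;
  double gmax = -1e300, gmin = 1e300;
  for (int t = 0; t < n; ++t) {
    bool up = (y[t] > 0) ? (alpha[t] < cost) : (alpha[t] > 0);
    bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < cost);
    double v = -y[t] * G[t];
    if (up && v > gmax) gmax = v;
    if (low && v < gmin) gmin = v;
    if (alpha[t] > 1e-10 && alpha[t] < cost - 1e-10) { bsum += v; ++bfree; }
  }
  double b = bfree > 0 ? bsum / bfree : 0.5 * (gmax + gmin);

  std::vector<int> sv_idx;
  for (int t = 0; t < n; ++t) if (alpha[t] > 1e-10) sv_idx.push_back(t);
  const int nsv = sv_idx.size();
  NumericMatrix SV(nsv, X.ncol());
  NumericVector coef(nsv);
  for (int k = 0; k < nsv; ++k) {
    int t = sv_idx[k];
    for (int j = 0; j < X.ncol(); ++j) SV(k, j) = X(t, j);
    coef[k] = alpha[t] * y[t];
  }
  return List::create(_["sv"] = SV, _["coef"] = coef, _["b"] = b,
                      _["iterations"] = iter, _["n_sv"] = nsv,
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()));
}

// Decision values f(x) = sum_k coef_k K(sv_k, x) + b for RBF kernel.
// [[Rcpp::export]]
NumericVector svm_rbf_decision_c(NumericMatrix SV, NumericVector coef,
                                 double b, double gamma, NumericMatrix Xnew) {
  const int nsv = SV.nrow(), d = SV.ncol(), m = Xnew.nrow();
  std::vector<double> svn(nsv);
  for (int k = 0; k < nsv; ++k) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) { double v = SV(k, j); s += v * v; }
    svn[k] = s;
  }
  std::vector<double> SVr((size_t)nsv * d);
  for (int k = 0; k < nsv; ++k)
    for (int j = 0; j < d; ++j) SVr[(size_t)k * d + j] = SV(k, j);
  NumericVector out(m);
  std::vector<double> xi(d);
  for (int i = 0; i < m; ++i) {
    double xn = 0.0;
    for (int j = 0; j < d; ++j) { xi[j] = Xnew(i, j); xn += xi[j] * xi[j]; }
    double f = b;
    for (int k = 0; k < nsv; ++k) {
      const double* pk = &SVr[(size_t)k * d];
      double dot = 0.0;
      for (int j = 0; j < d; ++j) dot += pk[j] * xi[j];
      f += coef[k] * std::exp(-gamma * (svn[k] + xn - 2.0 * dot));
    }
    out[i] = f;
  }
  return out;
}
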