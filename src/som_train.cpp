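#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Batch SOM training loop. Semantics match the R-level contract:
//  - BMU by squared Euclidean distance, ties to the lowest neuron index
//    (the per-row constant |x|^2 is dropped; it cannot change the argmin);
//  - neuron update = mean of rows whose BMU lies within link distance r(t);
//    neurons whose neighborhood captures no rows keep their weight;
//  - r(t) decays linearly from init_radius to min(1, init_radius) over the
//    first 90% of steps, is 0 afterwards, and is capped one hop below the
//    lattice diameter;
//  - once weights are stationary (max change < tol) the state cannot change
//    until the integer part of the radius does, so the loop jumps to the
//    next radius regime; in the radius-0 phase stationarity ends training.
// Data are copied into row-major buffers so the inner distance loop is
// contiguous.
// [[Rcpp::export]]
List som_batch_train_cpp(NumericMatrix X, NumericMatrix W0, IntegerMatrix ld,
                         int steps, double init_radius, double tol) {
  const int n = X.nrow(), p = X.ncol(), k = W0.nrow();

  std::vector<double> xr((size_t)n * p), wr((size_t)k * p);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) xr[(size_t)i * p + j] = X(i, j);
  for (int c = 0; c < k; ++c)
    for (int j = 0; j < p; ++j) wr[(size_t)c * p + j] = W0(c, j);

  std::vector<int> ldv((size_t)k * k);
  int max_ld = 0;
  for (int a = 0; a < k; ++a)
    for (int b = 0; b < k; ++b) {
      ldv[(size_t)a * k + b] = ld(a, b);
      if (ld(a, b) > max_ld) max_ld = ld(a, b);
    }
  const double r_cap = std::max(max_ld - 1, 0);
  const int t_switch = (int)std::floor(0.9 * steps);
  const double r_end = std::min(1.0, init_radius);

  std::vector<double> w2(k), S((size_t)k * p), num(p), wnew((size_t)k * p);
  std::vector<int> bmu(n), counts(k);

  auto radius_at = [&](int t) -> double {
    if (t > t_switch) return 0.0;
    double r = (t_switch <= 1)
      ? init_radius
      : init_radius - (init_radius - r_end) * (t - 1) / (double)(t_switch - 1);
    return std::min(r, r_cap);
  };

  int iterations = 0;
  int t = 1;
  while (t <= steps) {
    ++iterations;
    const double r = radius_at(t);

    for (int c = 0; c < k; ++c) {
      const double *w = &wr[(size_t)c * p];
      double s = 0.0;
      for (int j = 0; j < p; ++j) s += w[j] * w[j];
      w2[c] = s;
    }
    for (int i = 0; i < n; ++i) {
      const double *x = &xr[(size_t)i * p];
      double bestd = std::numeric_limits<double>::infinity();
      int best = 0;
      for (int c = 0; c < k; ++c) {
        const double *w = &wr[(size_t)c * p];
        double dot = 0.0;
        for (int j = 0; j < p; ++j) dot += x[j] * w[j];
        const double d = w2[c] - 2.0 * dot;
        if (d < bestd) { bestd = d; best = c; }
      }
      bmu[i] = best;
    }

    std::fill(counts.begin(), counts.end(), 0);
    std::fill(S.begin(), S.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const int c = bmu[i];
      ++counts[c];
      double *s = &S[(size_t)c * p];
      const double *x = &xr[(size_t)i * p];
      for (int j = 0; j < p; ++j) s[j] += x[j];
    }

    double delta = 0.0;
    for (int c = 0; c < k; ++c) {
      std::fill(num.begin(), num.end(), 0.0);
      long den = 0;
      const int *ldrow = &ldv[(size_t)c * k];
      for (int c2 = 0; c2 < k; ++c2) {
        if (ldrow[c2] <= r) {
          den += counts[c2];
          const double *s = &S[(size_t)c2 * p];
          for (int j = 0; j < p; ++j) num[j] += s[j];
        }
      }
      double *wn = &wnew[(size_t)c * p];
      const double *w = &wr[(size_t)c * p];
      for (int j = 0; j < p; ++j) {
        const double v = (den > 0) ? num[j] / (double)den : w[j];
        wn[j] = v;
        const double d = std::fabs(v - w[j]);
        if (d > delta) delta = d;
      }
    }
    wr.swap(wnew);

    if (delta < tol) {
      if (r <= 0.0) break;
      const double f = std::floor(r);
      int t2 = t + 1;
      while (t2 <= t_switch && std::floor(radius_at(t2)) == f) ++t2;
      t = t2;
    } else {
      ++t;
    }
  }

  NumericMatrix W(k, p);
  for (int c = 0; c < k; ++c)
    for (int j = 0; j < p; ++j) W(c, j) = wr[(size_t)c * p + j];
  return List::create(_["weights"] = W, _["iterations"] = iterations);
}
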