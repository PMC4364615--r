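#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double wrap_axis(double d, double L) {
  d = std::fabs(d);
  return d > L / 2.0 ? L - d : d;
}

// normalized per-axis feature difference; circular axes count a maximal
// (antipodal) separation as 1, linear axes use plain absolute difference
static inline double feat_diff(double a, double b, bool circular) {
  double d = std::fabs(a - b);
  if (circular) {
    if (d > 0.5) d = 1.0 - d;
    return 2.0 * d;
  }
  return d;
}

// Bernoulli edge sampling over all ordered pairs, one RNG draw per pair in
// (pre, post) order with post == pre skipped. Returns 1-based endpoint ids.
// use_tuning = FALSE drops the tuning factor (distance-only control).
// [[Rcpp::export]]
List cpp_sample_edges(NumericVector x, NumericVector y, NumericMatrix params,
                      double sheet_um, double pd_max, double td_max,
                      double pd_min, double p_scale, bool use_tuning,
                      LogicalVector circular) {
  const int n = x.size();
  const int k = params.ncol();
  std::vector<int> pre, post;
  std::vector<double> pd_v, td_v;
  size_t reserve = (size_t)std::max(16.0, 0.07 * (double)n * (double)n);
  pre.reserve(reserve); post.reserve(reserve);
  pd_v.reserve(reserve); td_v.reserve(reserve);

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = wrap_axis(x[i] - x[j], sheet_um);
      double dy = wrap_axis(y[i] - y[j], sheet_um);
      double pd = std::sqrt(dx * dx + dy * dy);
      if (pd < pd_min) pd = pd_min;
      double fd = 1.0 - pd / pd_max;
      if (fd < 0.0) fd = 0.0;
      double td = 0.0, p = fd;
      double s2 = 0.0;
      for (int c = 0; c < k; ++c) {
        double d = feat_diff(params(i, c), params(j, c), circular[c]);
        s2 += d * d;
      }
      td = std::sqrt(s2);
      if (use_tuning) {
        double ft = 1.0 - td / td_max;
        if (ft < 0.0) ft = 0.0;
        p *= ft;
      }
      p *= p_scale;
      double u = unif_rand();
      if (u < p) {
        pre.push_back(i + 1);
        post.push_back(j + 1);
        pd_v.push_back(pd);
        td_v.push_back(td);
      }
    }
  }
  return List::create(_["pre"] = IntegerVector(pre.begin(), pre.end()),
                      _["post"] = IntegerVector(post.begin(), post.end()),
                      _["pd"] = NumericVector(pd_v.begin(), pd_v.end()),
                      _["td"] = NumericVector(td_v.begin(), td_v.end()));
}

// Pairwise normalized tuning distance for small problems (used by the map
// module; vectorized over rows of `a` against the single row `b`).
// [[Rcpp::export]]
NumericVector cpp_tuning_distance(NumericMatrix a, NumericVector b,
                                  LogicalVector circular) {
  const int n = a.nrow(), k = a.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s2 = 0.0;
    for (int c = 0; c < k; ++c) {
      double d = feat_diff(a(i, c), b[c], circular[c]);
      s2 += d * d;
    }
    out[i] = std::sqrt(s2);
  }
  return out;
}
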