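#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Grouped summary statistics (mean, median, sd, iqr, max, p95) of `value`,
// where `key` is non-decreasing (values already grouped). Returns a list
// with the unique keys and one numeric vector per statistic. Quantiles are
// type 7 (linear interpolation of order statistics), matching
// stats::quantile's default.
static double q7(const std::vector<double> &sorted, double p) {
  const int n = (int)sorted.size();
  if (n == 1) return sorted[0];
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  int hi = std::min(lo + 1, n - 1);
  return sorted[lo] + (h - lo) * (sorted[hi] - sorted[lo]);
}

// [[Rcpp::export(name = ".group_seq_stats")]]
List group_seq_stats(NumericVector value, IntegerVector key) {
  const int n = value.size();
  std::vector<int> starts;
  for (int i = 0; i < n; ++i) {
    if (i == 0 || key[i] != key[i - 1]) starts.push_back(i);
  }
  const int g = (int)starts.size();
  IntegerVector out_key(g);
  NumericVector m(g), med(g), s(g), iqr(g), mx(g), p95(g);
  std::vector<double> buf;
  for (int gi = 0; gi < g; ++gi) {
    int a = starts[gi];
    int b = (gi + 1 < g) ? starts[gi + 1] : n;
    int len = b - a;
    out_key[gi] = key[a];
    buf.assign(value.begin() + a, value.begin() + b);
    std::sort(buf.begin(), buf.end());
    double sum = 0.0;
    for (int i = 0; i < len; ++i) sum += buf[i];
    double mu = sum / len;
    double ss = 0.0;
    for (int i = 0; i < len; ++i) ss += (buf[i] - mu) * (buf[i] - mu);
    m[gi] = mu;
    med[gi] = q7(buf, 0.5);
    s[gi] = (len > 1) ? std::sqrt(ss / (len - 1)) : NA_REAL;
    iqr[gi] = q7(buf, 0.75) - q7(buf, 0.25);
    mx[gi] = buf[len - 1];
    p95[gi] = q7(buf, 0.95);
  }
  return List::create(_["skey"] = out_key, _["mean"] = m, _["median"] = med,
                      _["sd"] = s, _["iqr"] = iqr, _["max"] = mx,
                      _["p95"] = p95);
}
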