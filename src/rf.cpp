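// Regression random-forest importance for regulator -> target scoring.
// Trees are grown on bootstrap samples; each node draws mtry candidate
// features and takes the split maximizing the reduction in sum of squared
// errors; a feature's importance accumulates the SSE reduction of every
// node it splits (impurity importance, as in tree-ensemble GRN scoring).
// Only importances are needed, so no predictions are stored.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

// deterministic xorshift64 RNG, independent of R's RNG and of compiler
// distribution implementations
struct XorShift {
  uint64_t s;
  explicit XorShift(uint32_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {
    for (int i = 0; i < 8; ++i) next();
  }
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  int bounded(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Node {
  int lo, hi; // index range into idx
};

void grow_tree(const NumericMatrix& X, const NumericVector& y,
               std::vector<int>& idx, int mtry, int min_split,
               XorShift& rng, std::vector<double>& imp) {
  const int p = X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  std::vector<Node> stack;
  stack.push_back({0, static_cast<int>(idx.size())});
  std::vector<std::pair<double, double>> xy;

  while (!stack.empty()) {
    Node nd = stack.back();
    stack.pop_back();
    const int n = nd.hi - nd.lo;
    if (n < min_split) continue;
    double sum = 0.0, sumsq = 0.0;
    for (int i = nd.lo; i < nd.hi; ++i) {
      const double v = y[idx[i]];
      sum += v;
      sumsq += v * v;
    }
    const double sse_parent = sumsq - sum * sum / n;
    if (sse_parent <= 1e-12) continue;

    // partial Fisher-Yates: first mtry entries of feats are the candidates
    for (int j = 0; j < mtry; ++j) {
      const int k = j + rng.bounded(p - j);
      std::swap(feats[j], feats[k]);
    }

    double best_red = 0.0, best_thr = 0.0;
    int best_f = -1;
    for (int j = 0; j < mtry; ++j) {
      const int f = feats[j];
      xy.clear();
      for (int i = nd.lo; i < nd.hi; ++i)
        xy.emplace_back(X(idx[i], f), y[idx[i]]);
      std::sort(xy.begin(), xy.end());
      if (xy.front().first == xy.back().first) continue;
      double lsum = 0.0, lsumsq = 0.0;
      double rsum = sum, rsumsq = sumsq;
      for (int i = 0; i < n - 1; ++i) {
        const double v = xy[i].second;
        lsum += v; lsumsq += v * v;
        rsum -= v; rsumsq -= v * v;
        if (xy[i].first == xy[i + 1].first) continue;
        const int nl = i + 1, nr = n - nl;
        const double sse = (lsumsq - lsum * lsum / nl) +
                           (rsumsq - rsum * rsum / nr);
        const double red = sse_parent - sse;
        if (red > best_red) {
          best_red = red;
          best_f = f;
          best_thr = 0.5 * (xy[i].first + xy[i + 1].first);
        }
      }
    }
    if (best_f < 0) continue;
    imp[best_f] += best_red;

    // partition idx[lo, hi) by the chosen threshold
    int mid = nd.lo;
    for (int i = nd.lo; i < nd.hi; ++i)
      if (X(idx[i], best_f) <= best_thr) std::swap(idx[mid++], idx[i]);
    if (mid == nd.lo || mid == nd.hi) continue; // numerical guard
    stack.push_back({nd.lo, mid});
    stack.push_back({mid, nd.hi});
  }
}

} // namespace

// [[Rcpp::export]]
NumericVector rf_importance_cpp(NumericMatrix X, NumericVector y,
                                int n_trees, int mtry, int min_split,
                                int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("X rows and y length differ");
  if (mtry < 1 || mtry > p) stop("mtry out of range");
  XorShift rng(static_cast<uint32_t>(seed));
  std::vector<double> imp(p, 0.0);
  std::vector<int> idx(n);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) idx[i] = rng.bounded(n); // bootstrap
    grow_tree(X, y, idx, mtry, min_split, rng, imp);
  }
  NumericVector out(p);
  for (int j = 0; j < p; ++j) out[j] = imp[j] / n_trees;
  return out;
}
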