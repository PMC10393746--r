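// Minimal CART random-forest classifier (binary), gini splits, bootstrap
// resampling with replacement, mtry features per node, grown to purity by
// default (min_node = 1). Out-of-bag predictions use the stored in-bag
// counts. Uses R's RNG so set.seed() in R gives full determinism.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <limits>
using namespace Rcpp;

namespace {

struct TreeBuf {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // split: x <= threshold goes left
  std::vector<int> left, right;
  std::vector<double> value;     // leaf: P(class 1)
};

int grow_node(const NumericMatrix &X, const IntegerVector &y,
              std::vector<int> &idx, int lo, int hi, // samples [lo, hi)
              int mtry, int min_node, TreeBuf &tb,
              std::vector<int> &feat_pool) {
  const int node = (int)tb.feature.size();
  tb.feature.push_back(-1);
  tb.threshold.push_back(0.0);
  tb.left.push_back(-1);
  tb.right.push_back(-1);

  const int n = hi - lo;
  int n1 = 0;
  for (int k = lo; k < hi; ++k) n1 += y[idx[k]];
  tb.value.push_back((double)n1 / n);
  if (n1 == 0 || n1 == n || n <= min_node) return node;

  const int p = X.ncol();
  // partial Fisher-Yates over the feature pool
  for (int k = 0; k < mtry; ++k) {
    int j = k + (int)(unif_rand() * (p - k));
    if (j >= p) j = p - 1;
    std::swap(feat_pool[k], feat_pool[j]);
  }

  double best_score = -std::numeric_limits<double>::infinity(),
         best_thr = 0.0;
  int best_feat = -1;
  std::vector<std::pair<double, int>> vals(n);
  for (int k = 0; k < mtry; ++k) {
    const int f = feat_pool[k];
    for (int a = 0; a < n; ++a) {
      const int s = idx[lo + a];
      vals[a] = std::make_pair(X(s, f), y[s]);
    }
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    int l1 = 0;
    for (int a = 0; a < n - 1; ++a) {
      l1 += vals[a].second;
      if (vals[a].first == vals[a + 1].first) continue;
      const int ln = a + 1, rn = n - ln;
      const int r1 = n1 - l1;
      // gini decrease up to constants: minimize sum of n0*n1/n per child
      const double score =
          -((double)l1 * (ln - l1) / ln + (double)r1 * (rn - r1) / rn);
      if (score > best_score) {
        best_score = score;
        best_feat = f;
        best_thr = 0.5 * (vals[a].first + vals[a + 1].first);
      }
    }
  }
  if (best_feat < 0) return node; // all candidates constant -> leaf

  // in-place partition of idx[lo, hi)
  int mid = lo;
  for (int k = lo; k < hi; ++k)
    if (X(idx[k], best_feat) <= best_thr) std::swap(idx[k], idx[mid++]);
  if (mid == lo || mid == hi) return node; // numeric ties: give up, leaf

  tb.feature[node] = best_feat;
  tb.threshold[node] = best_thr;
  tb.left[node] = grow_node(X, y, idx, lo, mid, mtry, min_node, tb, feat_pool);
  tb.right[node] = grow_node(X, y, idx, mid, hi, mtry, min_node, tb, feat_pool);
  return node;
}

inline double tree_predict(const IntegerVector &feature,
                           const NumericVector &threshold,
                           const IntegerVector &left,
                           const IntegerVector &right,
                           const NumericVector &value, int root,
                           const NumericMatrix &X, int row) {
  int node = root;
  while (feature[node] >= 0)
    node = (X(row, feature[node]) <= threshold[node]) ? left[node] : right[node];
  return value[node];
}

} // namespace

// [[Rcpp::export]]
List cpp_rf_fit(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                int min_node) {
  const int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  TreeBuf tb;
  std::vector<int> roots(n_trees), offsets(n_trees + 1, 0);
  IntegerMatrix inbag(n, n_trees);
  std::vector<int> idx(n), feat_pool(p);
  for (int f = 0; f < p; ++f) feat_pool[f] = f;

  for (int t = 0; t < n_trees; ++t) {
    for (int k = 0; k < n; ++k) {
      int s = (int)(unif_rand() * n);
      if (s >= n) s = n - 1;
      idx[k] = s;
      inbag(s, t)++;
    }
    roots[t] = grow_node(X, y, idx, 0, n, mtry, min_node, tb, feat_pool);
    offsets[t + 1] = (int)tb.feature.size();
  }
  return List::create(
      _["feature"] = wrap(tb.feature), _["threshold"] = wrap(tb.threshold),
      _["left"] = wrap(tb.left), _["right"] = wrap(tb.right),
      _["value"] = wrap(tb.value), _["root"] = wrap(roots),
      _["inbag"] = inbag, _["n_trees"] = n_trees);
}

// Per-row predicted probability of class 1. oob = true averages only over
// trees where the row was out of bag (requires X row-aligned with the
// training matrix); rows never out of bag yield NA.
// [[Rcpp::export]]
NumericVector cpp_rf_prob(List fit, NumericMatrix X, bool oob) {
  const IntegerVector feature = fit["feature"], left = fit["left"],
                      right = fit["right"], root = fit["root"];
  const NumericVector threshold = fit["threshold"], value = fit["value"];
  const IntegerMatrix inbag = fit["inbag"];
  const int n_trees = fit["n_trees"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    int m = 0;
    for (int t = 0; t < n_trees; ++t) {
      if (oob && inbag(i, t) > 0) continue;
      acc += tree_predict(feature, threshold, left, right, value, root[t], X, i);
      ++m;
    }
    out[i] = (m > 0) ? acc / m : NA_REAL;
  }
  return out;
}
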