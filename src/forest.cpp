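// Bagged regression-tree ensemble (random forest) used as the scoring
// regressor: bootstrap resampling, mtry feature subsampling, greedy
// variance-reduction splits, mean leaves. Uses R's RNG so fits are
// reproducible under set.seed().
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;      // split feature, -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;  // child node ids
  std::vector<double> value;     // leaf mean (valid when feature == -1)
};

inline int sample_int(int n) {  // uniform on 0..n-1 via R RNG
  int k = static_cast<int>(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

int grow(const NumericMatrix& X, const NumericVector& y,
         std::vector<int>& idx, int lo, int hi,  // node rows = idx[lo, hi)
         int mtry, int min_node, Tree& tree,
         std::vector<int>& feat_pool) {
  const int n = hi - lo;
  double sum = 0.0, sumsq = 0.0;
  for (int i = lo; i < hi; ++i) {
    sum += y[idx[i]];
    sumsq += y[idx[i]] * y[idx[i]];
  }
  const double mean = sum / n;
  const double sse = sumsq - sum * mean;

  const int node = static_cast<int>(tree.feature.size());
  tree.feature.push_back(-1);
  tree.threshold.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.value.push_back(mean);
  if (n <= min_node || sse <= 1e-12) return node;

  // choose mtry candidate features by partial Fisher-Yates
  const int K = X.ncol();
  for (int j = 0; j < K; ++j) feat_pool[j] = j;
  int best_feat = -1;
  double best_gain = 1e-12, best_thr = 0.0;

  std::vector<std::pair<double, double> > vals(n);  // (x, y) in node
  for (int m = 0; m < mtry; ++m) {
    const int r = m + sample_int(K - m);
    std::swap(feat_pool[m], feat_pool[r]);
    const int j = feat_pool[m];
    for (int i = 0; i < n; ++i) {
      vals[i].first = X(idx[lo + i], j);
      vals[i].second = y[idx[lo + i]];
    }
    std::sort(vals.begin(), vals.end());
    double sl = 0.0;  // running left sum
    for (int i = 0; i < n - 1; ++i) {
      sl += vals[i].second;
      if (vals[i + 1].first <= vals[i].first) continue;  // tied x
      const int nl = i + 1, nr = n - nl;
      const double sr = sum - sl;
      const double gain = sl * sl / nl + sr * sr / nr - sum * mean;
      if (gain > best_gain) {
        best_gain = gain;
        best_feat = j;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_feat < 0) return node;  // no admissible split among candidates

  // partition idx[lo,hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_feat) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return node;  // numeric degeneracy guard

  tree.feature[node] = best_feat;
  tree.threshold[node] = best_thr;
  tree.left[node] = grow(X, y, idx, lo, mid, mtry, min_node, tree, feat_pool);
  tree.right[node] = grow(X, y, idx, mid, hi, mtry, min_node, tree, feat_pool);
  return node;
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int ntree, int mtry,
                int min_node) {
  const int n = X.nrow();
  RNGScope scope;
  List trees(ntree);
  std::vector<int> idx(n), feat_pool(X.ncol());
  for (int t = 0; t < ntree; ++t) {
    for (int i = 0; i < n; ++i) idx[i] = sample_int(n);  // bootstrap
    Tree tree;
    grow(X, y, idx, 0, n, mtry, min_node, tree, feat_pool);
    trees[t] = List::create(
        _["feature"] = wrap(tree.feature), _["threshold"] = wrap(tree.threshold),
        _["left"] = wrap(tree.left), _["right"] = wrap(tree.right),
        _["value"] = wrap(tree.value));
  }
  return trees;
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    const List tr = trees[t];
    const IntegerVector feature = tr["feature"];
    const NumericVector threshold = tr["threshold"];
    const IntegerVector left = tr["left"], right = tr["right"];
    const NumericVector value = tr["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = X(i, feature[node]) <= threshold[node] ? left[node] : right[node];
      out[i] += value[node];
    }
  }
  return out / static_cast<double>(T);
}
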