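// Regression trees and forests with exhaustive midpoint split search,
// MSE impurity, and mean-decrease-impurity feature importance.
//
// Conventions fixed here and relied on by the R-side contracts and tests:
//  * candidate thresholds are midpoints between consecutive distinct sorted
//    values of a feature within the node;
//  * the chosen split strictly minimises the weighted child impurity
//    G = (n_left * H_left + n_right * H_right) / N_s, ties broken by lowest
//    feature index then lowest threshold (features are scanned in ascending
//    index order and thresholds in ascending order with strict improvement);
//  * node importance uses weights relative to the root sample count:
//    n_k = w_k H_k - w_left H_left - w_right H_right, w = n_node / n_root,
//    so per-tree importances telescope to root impurity minus the weighted
//    leaf impurity sum.
// All randomness (bootstrap draws, per-node feature subsets) comes from R's
// RNG stream, so results are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct TreeArrays {
  std::vector<int> feature;      // split feature (0-based), -1 for leaf
  std::vector<double> threshold; // split value, NA for leaf
  std::vector<int> left, right;  // child node ids, -1 for leaf
  std::vector<int> n_node;       // training samples in node
  std::vector<double> impurity;  // H(X): node MSE
  std::vector<double> value;     // mean response in node
};

struct SplitResult {
  bool found = false;
  int feature = -1;
  double threshold = 0.0;
  double score = 0.0; // weighted child impurity G
};

inline double node_mse(const std::vector<int>& idx, const NumericVector& y,
                       double mean) {
  double ss = 0.0;
  for (int i : idx) {
    const double d = y[i] - mean;
    ss += d * d;
  }
  return ss / idx.size();
}

// Draw `k` distinct feature indices out of `m` using R's RNG, return sorted.
std::vector<int> sample_features(int m, int k) {
  std::vector<int> pool(m);
  for (int i = 0; i < m; ++i) pool[i] = i;
  for (int i = 0; i < k; ++i) {
    int j = i + (int)std::floor(unif_rand() * (m - i));
    if (j >= m) j = m - 1;
    std::swap(pool[i], pool[j]);
  }
  pool.resize(k);
  std::sort(pool.begin(), pool.end());
  return pool;
}

// Best split for one node over the given feature subset (already sorted
// ascending, which realises the lowest-feature-index tie rule).
SplitResult best_split(const NumericMatrix& X, const NumericVector& y,
                       const std::vector<int>& idx,
                       const std::vector<int>& feats, int min_leaf) {
  const int n = (int)idx.size();
  SplitResult best;
  std::vector<std::pair<double, double>> xv(n); // (x, y) sorted by x

  for (int f : feats) {
    for (int i = 0; i < n; ++i)
      xv[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
    std::sort(xv.begin(), xv.end());
    if (xv.front().first == xv.back().first) continue; // constant feature

    // prefix sums of y and y^2 in x-order
    double sl = 0.0, ssl = 0.0;
    double st = 0.0, sst = 0.0;
    for (int i = 0; i < n; ++i) {
      st += xv[i].second;
      sst += xv[i].second * xv[i].second;
    }
    for (int k = 1; k < n; ++k) {
      sl += xv[k - 1].second;
      ssl += xv[k - 1].second * xv[k - 1].second;
      if (xv[k - 1].first == xv[k].first) continue; // not a boundary
      const int nl = k, nr = n - k;
      if (nl < min_leaf || nr < min_leaf) continue;
      const double sr = st - sl, ssr = sst - ssl;
      const double sse_l = ssl - sl * sl / nl;
      const double sse_r = ssr - sr * sr / nr;
      const double score = (sse_l + sse_r) / n; // (n_l H_l + n_r H_r) / N_s
      // strict improvement beyond a relative tolerance: mathematically tied
      // candidates keep the earlier (lowest feature, lowest threshold) one
      if (!best.found ||
          score < best.score - 1e-12 * (1.0 + std::abs(best.score))) {
        best.found = true;
        best.feature = f;
        best.threshold = 0.5 * (xv[k - 1].first + xv[k].first);
        best.score = score;
      }
    }
  }
  return best;
}

int grow(const NumericMatrix& X, const NumericVector& y,
         const std::vector<int>& idx, TreeArrays& t, int mtry, int min_split,
         int min_leaf) {
  const int m = X.ncol();
  const int n = (int)idx.size();
  double mean = 0.0;
  for (int i : idx) mean += y[i];
  mean /= n;
  const double h = node_mse(idx, y, mean);

  const int id = (int)t.feature.size();
  t.feature.push_back(-1);
  t.threshold.push_back(NA_REAL);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.n_node.push_back(n);
  t.impurity.push_back(h);
  t.value.push_back(mean);

  if (n < min_split || h <= 0.0) return id;

  std::vector<int> feats = sample_features(m, mtry);
  SplitResult sp = best_split(X, y, idx, feats, min_leaf);
  if (!sp.found) return id;

  std::vector<int> li, ri;
  li.reserve(n);
  ri.reserve(n);
  for (int i : idx) {
    if (X(i, sp.feature) <= sp.threshold) li.push_back(i);
    else ri.push_back(i);
  }
  if (li.empty() || ri.empty()) return id; // numerical guard

  t.feature[id] = sp.feature;
  t.threshold[id] = sp.threshold;
  const int lid = grow(X, y, li, t, mtry, min_split, min_leaf);
  t.left[id] = lid;
  const int rid = grow(X, y, ri, t, mtry, min_split, min_leaf);
  t.right[id] = rid;
  return id;
}

// Per-tree normalised feature importance (sums to one; all-NA when the tree
// has no internal node).
NumericVector tree_importance(const TreeArrays& t, int m) {
  NumericVector f(m, 0.0);
  const double n_root = (double)t.n_node[0];
  double total = 0.0;
  bool any = false;
  for (size_t k = 0; k < t.feature.size(); ++k) {
    if (t.feature[k] < 0) continue;
    any = true;
    const int l = t.left[k], r = t.right[k];
    const double nk = (t.n_node[k] / n_root) * t.impurity[k] -
                      (t.n_node[l] / n_root) * t.impurity[l] -
                      (t.n_node[r] / n_root) * t.impurity[r];
    f[t.feature[k]] += nk;
    total += nk;
  }
  if (!any || total <= 0.0) {
    std::fill(f.begin(), f.end(), NA_REAL);
    return f;
  }
  for (int i = 0; i < m; ++i) f[i] /= total;
  double s = 0.0;
  for (int i = 0; i < m; ++i) s += f[i];
  for (int i = 0; i < m; ++i) f[i] /= s; // final renormalisation
  return f;
}

List tree_to_list(const TreeArrays& t) {
  return List::create(
      _["feature"] = wrap(t.feature), _["threshold"] = wrap(t.threshold),
      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
      _["n_node"] = wrap(t.n_node), _["impurity"] = wrap(t.impurity),
      _["value"] = wrap(t.value));
}

double predict_one(const List& tree, const NumericMatrix& X, int row) {
  const IntegerVector feature = tree["feature"];
  const NumericVector threshold = tree["threshold"];
  const IntegerVector left = tree["left"];
  const IntegerVector right = tree["right"];
  const NumericVector value = tree["value"];
  int k = 0;
  while (feature[k] >= 0)
    k = (X(row, feature[k]) <= threshold[k]) ? left[k] : right[k];
  return value[k];
}

} // namespace

// [[Rcpp::export]]
List cpp_fit_forest(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                    int min_split, int min_leaf, bool bootstrap) {
  const int n = X.nrow(), m = X.ncol();
  RNGScope scope;
  List trees(n_trees);
  NumericMatrix imp(n_trees, m);

  for (int b = 0; b < n_trees; ++b) {
    std::vector<int> idx(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) {
        int j = (int)std::floor(unif_rand() * n);
        if (j >= n) j = n - 1;
        idx[i] = j;
      }
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    TreeArrays t;
    grow(X, y, idx, t, mtry, min_split, min_leaf);
    trees[b] = tree_to_list(t);
    imp(b, _) = tree_importance(t, m);
  }
  return List::create(_["trees"] = trees, _["importance"] = imp);
}

// [[Rcpp::export]]
NumericVector cpp_predict_forest(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int B = trees.size();
  NumericVector out(n, 0.0);
  for (int b = 0; b < B; ++b) {
    const List tree = trees[b];
    for (int i = 0; i < n; ++i) out[i] += predict_one(tree, X, i);
  }
  return out / (double)B;
}
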