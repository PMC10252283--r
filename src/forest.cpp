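// Bagged CART growing for the nine-predictor panel classifier.
// Trees use axis-aligned splits chosen by Gini impurity over a random
// feature subset per node. All randomness comes from a self-contained
// splitmix64 stream seeded per tree from R, so results are identical
// across platforms and independent of R's global RNG state.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // deterministic bounded draw; modulo bias is irrelevant here
  int bounded(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

inline double gini(double n1, double n) {
  if (n <= 0.0) return 0.0;
  double p = n1 / n;
  return 2.0 * p * (1.0 - p);
}

struct TreeBuf {
  std::vector<int> feature;      // 0-based split feature, -1 for leaf
  std::vector<double> threshold; // x <= threshold goes left
  std::vector<int> left, right;  // 0-based child ids, -1 for leaf
  std::vector<double> prob;      // node fraction of class 1 (HSIL)
  int add_node() {
    feature.push_back(-1);
    threshold.push_back(NA_REAL);
    left.push_back(-1);
    right.push_back(-1);
    prob.push_back(NA_REAL);
    return static_cast<int>(feature.size()) - 1;
  }
};

struct Grower {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry, max_depth, min_leaf, n_total, p;
  SplitMix64& rng;
  TreeBuf& tree;
  std::vector<double>& importance; // accumulated impurity decrease

  int grow(std::vector<int>& idx, int depth) {
    int node = tree.add_node();
    int m = static_cast<int>(idx.size());
    int n1 = 0;
    for (int i : idx) n1 += y[i];
    tree.prob[node] = static_cast<double>(n1) / m;
    bool pure = (n1 == 0 || n1 == m);
    if (pure || m < 2 * min_leaf || (max_depth >= 0 && depth >= max_depth)) {
      return node;
    }

    // draw mtry distinct features (partial Fisher-Yates)
    std::vector<int> feats(p);
    for (int f = 0; f < p; ++f) feats[f] = f;
    for (int j = 0; j < mtry; ++j) {
      int k = j + rng.bounded(p - j);
      std::swap(feats[j], feats[k]);
    }

    double g_parent = gini(n1, m);
    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<std::pair<double, int>> vals(m);
    for (int j = 0; j < mtry; ++j) {
      int f = feats[j];
      for (int i = 0; i < m; ++i) {
        vals[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
      }
      std::sort(vals.begin(), vals.end());
      int left1 = 0;
      for (int i = 0; i < m - 1; ++i) {
        left1 += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        int nl = i + 1, nr = m - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        double gain = g_parent -
          (static_cast<double>(nl) / m) * gini(left1, nl) -
          (static_cast<double>(nr) / m) * gini(n1 - left1, nr);
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) return node; // no informative split among drawn features

    importance[best_f] += (static_cast<double>(m) / n_total) * best_gain;
    std::vector<int> idx_l, idx_r;
    idx_l.reserve(m);
    idx_r.reserve(m);
    for (int i : idx) {
      (X(i, best_f) <= best_thr ? idx_l : idx_r).push_back(i);
    }
    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    tree.left[node] = grow(idx_l, depth + 1);
    tree.right[node] = grow(idx_r, depth + 1);
    return node;
  }
};

List tree_to_list(const TreeBuf& t) {
  int n = static_cast<int>(t.feature.size());
  IntegerVector feature(n), left(n), right(n);
  NumericVector threshold(n), prob(n);
  for (int i = 0; i < n; ++i) {
    feature[i] = t.feature[i] < 0 ? NA_INTEGER : t.feature[i] + 1;
    left[i] = t.left[i] < 0 ? NA_INTEGER : t.left[i] + 1;
    right[i] = t.right[i] < 0 ? NA_INTEGER : t.right[i] + 1;
    threshold[i] = t.threshold[i];
    prob[i] = t.prob[i];
  }
  return List::create(
    Named("feature") = feature, Named("threshold") = threshold,
    Named("left") = left, Named("right") = right, Named("prob") = prob);
}

} // namespace

// [[Rcpp::export(name = ".grow_forest_cpp")]]
List grow_forest_cpp(NumericMatrix X, IntegerVector y, int mtry,
                     int max_depth, int min_leaf, bool bootstrap,
                     NumericVector tree_seeds) {
  int n = X.nrow(), p = X.ncol();
  int n_trees = tree_seeds.size();
  if (n < 1) stop("empty predictor matrix");
  if (y.size() != n) stop("y length must match nrow(X)");
  List trees(n_trees);
  std::vector<double> importance(p, 0.0);
  for (int t = 0; t < n_trees; ++t) {
    SplitMix64 rng(static_cast<uint64_t>(tree_seeds[t]));
    std::vector<int> idx(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) idx[i] = rng.bounded(n);
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    TreeBuf buf;
    Grower g{X, y, mtry, max_depth, min_leaf, n, p, rng, buf, importance};
    g.grow(idx, 0);
    trees[t] = tree_to_list(buf);
  }
  return List::create(
    Named("trees") = trees,
    Named("importance_raw") = NumericVector(importance.begin(),
                                            importance.end()));
}

// [[Rcpp::export(name = ".predict_forest_cpp")]]
NumericVector predict_forest_cpp(List trees, NumericMatrix X) {
  int n = X.nrow();
  int n_trees = trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < n_trees; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"],
                  right = tr["right"];
    NumericVector threshold = tr["threshold"], prob = tr["prob"];
    int n_nodes = feature.size();
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] != NA_INTEGER) {
        int f = feature[node] - 1;
        if (f < 0 || f >= X.ncol()) stop("malformed tree: bad feature index");
        node = (X(i, f) <= threshold[node] ? left[node] : right[node]) - 1;
        if (node < 0 || node >= n_nodes) stop("malformed tree: bad child id");
      }
      out[i] += prob[node];
    }
  }
  return out / static_cast<double>(n_trees);
}
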