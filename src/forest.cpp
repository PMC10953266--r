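// Compact CART random forest for binary classification, following the
// common sklearn defaults: Gini criterion, bootstrap resampling,
// mtry = floor(sqrt(p)) candidate features per split, min_samples_split = 2,
// min_samples_leaf = 1, optional max depth cap. Mean-decrease-impurity
// feature importances are normalized per tree and averaged across the
// forest. A private mt19937 keeps tree growth deterministic given a seed,
// independent of R's RNG state.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

struct Node {
  int feat = -1;       // -1 marks a leaf
  double thr = 0.0;
  int left = -1, right = -1;
  double prob = 0.0;   // class-1 fraction (leaf)
};

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry, max_depth;  // max_depth <= 0 means unbounded
  std::mt19937& rng;
  std::vector<Node> nodes;
  std::vector<double> importance;  // impurity decrease, weighted by n/n_root
  double n_root;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
              int max_depth_, std::mt19937& rng_)
      : X(X_), y(y_), mtry(mtry_), max_depth(max_depth_), rng(rng_),
        importance(X_.ncol(), 0.0), n_root(0.0) {}

  static double gini(double n1, double n) {
    if (n <= 0.0) return 0.0;
    double p = n1 / n;
    return 2.0 * p * (1.0 - p);
  }

  int build(std::vector<int>& idx, int depth) {
    const int n = (int)idx.size();
    double n1 = 0.0;
    for (int i : idx) n1 += y[i];
    const double imp = gini(n1, n);
    const int me = (int)nodes.size();
    nodes.push_back(Node());
    nodes[me].prob = n > 0 ? n1 / n : 0.0;
    const bool can_split =
        n >= 2 && imp > 0.0 && (max_depth <= 0 || depth < max_depth);
    if (!can_split) return me;

    // sample mtry features without replacement
    const int p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    for (int j = 0; j < mtry; ++j) {
      std::uniform_int_distribution<int> d(j, p - 1);
      std::swap(feats[j], feats[d(rng)]);
    }

    int best_feat = -1;
    double best_thr = 0.0, best_gain = 1e-12;
    std::vector<std::pair<double, int>> vals(n);
    for (int jj = 0; jj < mtry; ++jj) {
      const int f = feats[jj];
      for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], f), y[idx[i]]};
      std::sort(vals.begin(), vals.end());
      double left1 = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        left1 += vals[i].second;
        if (vals[i + 1].first <= vals[i].first) continue;  // tied values
        const double nl = i + 1, nr = n - nl;
        const double gain =
            imp - (nl / n) * gini(left1, nl) - (nr / n) * gini(n1 - left1, nr);
        if (gain > best_gain) {
          best_gain = gain;
          best_feat = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_feat < 0) return me;

    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_feat) <= best_thr) li.push_back(i); else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) return me;
    importance[best_feat] += (n / n_root) * best_gain;
    nodes[me].feat = best_feat;
    nodes[me].thr = best_thr;
    nodes[me].left = build(li, depth + 1);
    nodes[me].right = build(ri, depth + 1);
    return me;
  }
};

// [[Rcpp::export(name = ".rf_build_cpp")]]
List rf_build_cpp(const NumericMatrix& X, const IntegerVector& y, int n_trees,
                  int max_depth, int mtry, unsigned int seed) {
  const int n = X.nrow(), p = X.ncol();
  std::mt19937 rng(seed);
  List trees(n_trees);
  NumericVector imp(p);
  std::uniform_int_distribution<int> boot(0, n - 1);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    TreeBuilder tb(X, y, mtry, max_depth, rng);
    tb.n_root = n;
    tb.build(idx, 0);
    const int m = (int)tb.nodes.size();
    NumericMatrix nm(m, 5);  // feat thr left right prob
    for (int k = 0; k < m; ++k) {
      nm(k, 0) = tb.nodes[k].feat;
      nm(k, 1) = tb.nodes[k].thr;
      nm(k, 2) = tb.nodes[k].left;
      nm(k, 3) = tb.nodes[k].right;
      nm(k, 4) = tb.nodes[k].prob;
    }
    trees[t] = nm;
    double tot = 0.0;
    for (double v : tb.importance) tot += v;
    if (tot > 0.0)
      for (int j = 0; j < p; ++j) imp[j] += tb.importance[j] / tot;
  }
  for (int j = 0; j < p; ++j) imp[j] /= n_trees;
  return List::create(_["trees"] = trees, _["importance"] = imp);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(const List& trees, const NumericMatrix& X) {
  const int n = X.nrow(), nt = trees.size();
  NumericVector out(n);
  for (int t = 0; t < nt; ++t) {
    NumericMatrix nm = trees[t];
    for (int i = 0; i < n; ++i) {
      int k = 0;
      while (nm(k, 0) >= 0) {
        k = (X(i, (int)nm(k, 0)) <= nm(k, 1)) ? (int)nm(k, 2) : (int)nm(k, 3);
      }
      out[i] += nm(k, 4);
    }
  }
  return out / (double)nt;
}
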