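// A compact CART random forest for binary classification.
//
// Trees are grown on bootstrap samples with mtry features considered per
// split, Gini impurity, and no depth limit (nodes split until pure or below
// the minimum size). Predictions average the leaf class-1 fractions over
// trees; variable importance is the bootstrap-weighted mean decrease in Gini,
// normalized to sum to one. A private mt19937 keeps fits reproducible and
// independent of R's RNG.

#include "rfaradiomics_types.h"

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <random>
#include <cstdint>

using namespace Rcpp;

static void grow_node(const NumericMatrix& X, const IntegerVector& y,
                      std::vector<int>& idx, int lo, int hi,
                      Tree& tree, int node_id, int mtry, int min_node,
                      std::mt19937& rng, std::vector<double>& imp,
                      int n_total) {
  const int n = hi - lo;
  int n1 = 0;
  for (int i = lo; i < hi; ++i) n1 += y[idx[i]];
  tree.nodes[node_id].prob1 = static_cast<double>(n1) / n;
  if (n1 == 0 || n1 == n || n < 2 * min_node) return;

  const double p1 = static_cast<double>(n1) / n;
  const double gini_parent = 2.0 * p1 * (1.0 - p1);
  const int p = X.ncol();

  // sample mtry distinct candidate features
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  for (int j = 0; j < mtry && j < p; ++j) {
    std::uniform_int_distribution<int> U(j, p - 1);
    std::swap(feats[j], feats[U(rng)]);
  }

  double best_gain = 1e-12;
  int best_feat = -1;
  double best_thr = 0.0;

  std::vector<std::pair<double, int>> vals(n);
  for (int jj = 0; jj < mtry && jj < p; ++jj) {
    const int f = feats[jj];
    for (int i = 0; i < n; ++i) {
      const int r = idx[lo + i];
      vals[i] = std::make_pair(X(r, f), y[r]);
    }
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    int left1 = 0;
    for (int i = 0; i < n - 1; ++i) {
      left1 += vals[i].second;
      if (vals[i].first == vals[i + 1].first) continue;
      const int nl = i + 1, nr = n - nl;
      if (nl < min_node || nr < min_node) continue;
      const double pl = static_cast<double>(left1) / nl;
      const double pr = static_cast<double>(n1 - left1) / nr;
      const double gini = (nl * 2.0 * pl * (1.0 - pl) + nr * 2.0 * pr * (1.0 - pr)) / n;
      const double gain = gini_parent - gini;
      if (gain > best_gain) {
        best_gain = gain;
        best_feat = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_feat < 0) return;

  // weighted impurity decrease for importance
  imp[best_feat] += best_gain * n / n_total;

  // partition idx[lo:hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_feat) <= best_thr) std::swap(idx[i], idx[mid++]);

  Node& nd = tree.nodes[node_id];
  nd.feature = best_feat;
  nd.threshold = best_thr;
  const int left_id = static_cast<int>(tree.nodes.size());
  tree.nodes.push_back(Node());
  const int right_id = static_cast<int>(tree.nodes.size());
  tree.nodes.push_back(Node());
  tree.nodes[node_id].left = left_id;
  tree.nodes[node_id].right = right_id;
  grow_node(X, y, idx, lo, mid, tree, left_id, mtry, min_node, rng, imp, n_total);
  grow_node(X, y, idx, mid, hi, tree, right_id, mtry, min_node, rng, imp, n_total);
}

// [[Rcpp::export(name = ".rf_fit_cpp")]]
XPtr<Forest> rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_trees,
                        int mtry, int min_node, int seed) {
  const int n = X.nrow(), p = X.ncol();
  Forest* forest = new Forest();
  forest->p = p;
  forest->importance.assign(p, 0.0);
  std::mt19937 rng(static_cast<std::uint32_t>(seed));
  std::uniform_int_distribution<int> boot(0, n - 1);
  std::vector<int> idx(n);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    Tree tree;
    tree.nodes.push_back(Node());
    grow_node(X, y, idx, 0, n, tree, 0, mtry, min_node, rng,
              forest->importance, n);
    forest->trees.push_back(std::move(tree));
  }
  double tot = 0.0;
  for (int j = 0; j < p; ++j) tot += forest->importance[j];
  if (tot > 0)
    for (int j = 0; j < p; ++j) forest->importance[j] /= tot;
  return XPtr<Forest>(forest, true);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(XPtr<Forest> forest, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n);
  const int T = static_cast<int>(forest->trees.size());
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int t = 0; t < T; ++t) {
      const Tree& tree = forest->trees[t];
      int node = 0;
      while (tree.nodes[node].feature >= 0) {
        node = (X(i, tree.nodes[node].feature) <= tree.nodes[node].threshold)
                 ? tree.nodes[node].left : tree.nodes[node].right;
      }
      acc += tree.nodes[node].prob1;
    }
    out[i] = acc / T;
  }
  return out;
}

// [[Rcpp::export(name = ".rf_importance_cpp")]]
NumericVector rf_importance_cpp(XPtr<Forest> forest) {
  return NumericVector(forest->importance.begin(), forest->importance.end());
}
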