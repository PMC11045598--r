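// Bagged CART classification forest: Gini impurity splits, per-node random
// feature subsets (mtry), bootstrap resampling per tree, majority-vote
// prediction. Uses R's RNG so results are reproducible via set.seed().
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct Node {
  int feature;      // -1 for leaf
  double threshold; // split: x <= threshold goes left
  int left, right;  // child indices
  int pred;         // leaf class (0-based)
};

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int n_classes, mtry, min_node, max_depth;
  std::vector<Node> nodes;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int K,
              int mtry_, int min_node_, int max_depth_)
    : X(X_), y(y_), n_classes(K), mtry(mtry_), min_node(min_node_),
      max_depth(max_depth_) {}

  int majority(const std::vector<int>& idx) {
    std::vector<int> cnt(n_classes, 0);
    for (int i : idx) cnt[y[i]]++;
    return (int)(std::max_element(cnt.begin(), cnt.end()) - cnt.begin());
  }

  bool pure(const std::vector<int>& idx) {
    for (size_t i = 1; i < idx.size(); ++i)
      if (y[idx[i]] != y[idx[0]]) return false;
    return true;
  }

  int build(std::vector<int>& idx, int depth) {
    int me = (int)nodes.size();
    nodes.push_back(Node{-1, 0.0, -1, -1, majority(idx)});
    if ((int)idx.size() <= min_node || depth >= max_depth || pure(idx))
      return me;

    int p = X.ncol();
    // sample mtry features without replacement (R RNG)
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    for (int j = 0; j < mtry; ++j) {
      int k = j + (int)(unif_rand() * (p - j));
      if (k >= p) k = p - 1;
      std::swap(feats[j], feats[k]);
    }

    double n = (double)idx.size();
    std::vector<int> total(n_classes, 0);
    for (int i : idx) total[y[i]]++;
    double best_gain = 1e-12, parent_imp = 1.0;
    for (int c = 0; c < n_classes; ++c)
      parent_imp -= (total[c] / n) * (total[c] / n);
    int best_f = -1;
    double best_thr = 0.0;

    std::vector<int> ord(idx);
    for (int fj = 0; fj < mtry; ++fj) {
      int f = feats[fj];
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        double xa = X(a, f), xb = X(b, f);
        if (xa != xb) return xa < xb;
        return a < b;
      });
      std::vector<int> lc(n_classes, 0);
      for (size_t i = 0; i + 1 < ord.size(); ++i) {
        lc[y[ord[i]]]++;
        double xi = X(ord[i], f), xn = X(ord[i + 1], f);
        if (xi == xn) continue;
        double nl = (double)(i + 1), nr = n - nl;
        double il = 1.0, ir = 1.0;
        for (int c = 0; c < n_classes; ++c) {
          double pl = lc[c] / nl, pr = (total[c] - lc[c]) / nr;
          il -= pl * pl;
          ir -= pr * pr;
        }
        double gain = parent_imp - (nl / n) * il - (nr / n) * ir;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (xi + xn);
        }
      }
    }
    if (best_f < 0) return me;

    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) li.push_back(i);
      else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) return me;
    nodes[me].feature = best_f;
    nodes[me].threshold = best_thr;
    int l = build(li, depth + 1);
    nodes[me].left = l;
    int r = build(ri, depth + 1);
    nodes[me].right = r;
    return me;
  }
};

// [[Rcpp::export(name = ".rf_fit")]]
List rf_fit(NumericMatrix X, IntegerVector y, int n_classes, int n_trees,
            int mtry, int min_node, int max_depth) {
  RNGScope scope;
  int n = X.nrow();
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * n);
      if (k >= n) k = n - 1;
      idx[i] = k;
    }
    TreeBuilder tb(X, y, n_classes, mtry, min_node, max_depth);
    tb.build(idx, 0);
    int m = (int)tb.nodes.size();
    IntegerVector feature(m), left(m), right(m), pred(m);
    NumericVector threshold(m);
    for (int i = 0; i < m; ++i) {
      feature[i] = tb.nodes[i].feature;
      threshold[i] = tb.nodes[i].threshold;
      left[i] = tb.nodes[i].left;
      right[i] = tb.nodes[i].right;
      pred[i] = tb.nodes[i].pred;
    }
    trees[t] = List::create(_["feature"] = feature,
                            _["threshold"] = threshold, _["left"] = left,
                            _["right"] = right, _["pred"] = pred);
  }
  return trees;
}

// [[Rcpp::export(name = ".rf_predict")]]
IntegerMatrix rf_predict(List trees, NumericMatrix X, int n_classes) {
  int n = X.nrow(), T = trees.size();
  IntegerMatrix votes(n, n_classes);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"],
                  right = tr["right"], pred = tr["pred"];
    NumericVector threshold = tr["threshold"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      }
      votes(i, pred[node])++;
    }
  }
  return votes;
}
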