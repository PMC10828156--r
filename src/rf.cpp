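// Random forest for regression and binary classification.
//
// CART trees with bootstrap resampling, per-node feature subsampling
// (mtry) and depth limiting. Binary classification uses 0/1 labels, for
// which variance reduction is proportional to the Gini gain, so one split
// criterion serves both tasks; class probabilities are leaf means
// averaged over trees. Importances are bootstrap-weighted impurity
// decreases, normalized per forest.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> value;
};

static void build_node(const NumericMatrix& X, const NumericVector& y,
                       std::vector<int>& idx, int lo, int hi, int depth,
                       int max_depth, int mtry, int min_split,
                       Tree& tree, std::mt19937& rng,
                       std::vector<double>& importance) {
  int node = (int)tree.feature.size();
  tree.feature.push_back(-1);
  tree.threshold.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);

  int n = hi - lo;
  double sum = 0.0, sumsq = 0.0;
  for (int i = lo; i < hi; ++i) {
    double v = y[idx[i]];
    sum += v; sumsq += v * v;
  }
  double mean = sum / n;
  tree.value.push_back(mean);
  double sse = sumsq - sum * sum / n;

  if (n < min_split || sse <= 1e-12 ||
      (max_depth >= 0 && depth >= max_depth))
    return;

  int p = X.ncol();
  // sample mtry features without replacement (partial Fisher-Yates)
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {
    std::uniform_int_distribution<int> d(j, p - 1);
    std::swap(feats[j], feats[d(rng)]);
  }

  double best_gain = 1e-12;
  int best_feat = -1;
  double best_thr = 0.0;

  std::vector<std::pair<double,double> > vals(n);
  for (int jj = 0; jj < m; ++jj) {
    int f = feats[jj];
    for (int i = 0; i < n; ++i) {
      int r = idx[lo + i];
      vals[i] = std::make_pair(X(r, f), y[r]);
    }
    std::sort(vals.begin(), vals.end());
    if (vals[0].first == vals[n - 1].first) continue;
    double lsum = 0.0, lsq = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      double v = vals[i].second;
      lsum += v; lsq += v * v;
      if (vals[i + 1].first <= vals[i].first) continue;
      int nl = i + 1, nr = n - nl;
      double rsum = sum - lsum, rsq = sumsq - lsq;
      double sse_l = lsq - lsum * lsum / nl;
      double sse_r = rsq - rsum * rsum / nr;
      double gain = sse - sse_l - sse_r;
      if (gain > best_gain) {
        best_gain = gain;
        best_feat = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_feat < 0) return;

  // partition idx[lo, hi) by the chosen split
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_feat) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return;

  importance[best_feat] += best_gain;
  tree.feature[node] = best_feat;
  tree.threshold[node] = best_thr;
  tree.left[node] = (int)tree.feature.size();
  build_node(X, y, idx, lo, mid, depth + 1, max_depth, mtry, min_split,
             tree, rng, importance);
  tree.right[node] = (int)tree.feature.size();
  build_node(X, y, idx, mid, hi, depth + 1, max_depth, mtry, min_split,
             tree, rng, importance);
}

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int n_trees,
                int max_depth, int mtry, int min_split, int seed) {
  int n = X.nrow(), p = X.ncol();
  if (n < 1 || y.size() != n) stop("rf_fit_cpp: dimension mismatch");
  List trees(n_trees);
  std::vector<double> importance(p, 0.0);
  for (int t = 0; t < n_trees; ++t) {
    std::mt19937 rng((unsigned)(seed + 1000003 * (t + 1)));
    std::uniform_int_distribution<int> boot(0, n - 1);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    Tree tree;
    build_node(X, y, idx, 0, n, 0, max_depth, mtry, min_split,
               tree, rng, importance);
    trees[t] = List::create(
      _["feature"] = IntegerVector(tree.feature.begin(), tree.feature.end()),
      _["threshold"] = NumericVector(tree.threshold.begin(), tree.threshold.end()),
      _["left"] = IntegerVector(tree.left.begin(), tree.left.end()),
      _["right"] = IntegerVector(tree.right.begin(), tree.right.end()),
      _["value"] = NumericVector(tree.value.begin(), tree.value.end()));
  }
  double tot = 0.0;
  for (int j = 0; j < p; ++j) tot += importance[j];
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = tot > 0 ? importance[j] / tot : 0.0;
  return List::create(_["trees"] = trees, _["importance"] = imp,
                      _["n_features"] = p);
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  List trees = forest["trees"];
  int n = X.nrow(), nt = trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < nt; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector value = tr["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      out[i] += value[node];
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= nt;
  return out;
}
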