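// Random-forest classifier: CART trees, Gini impurity, bootstrap resampling,
// mtry features per split.  Uses R's RNG so set.seed() on the R side gives
// full reproducibility.  Written in-package because no tree/forest package is
// available in the target library.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;      // split feature, -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;  // child node ids
  std::vector<double> pred;      // leaf positive-class fraction
};

const int MAX_DEPTH = 40;
const double EPS = 1e-12;

int randInt(int n) {  // uniform on 0..n-1 via R's RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Grow a node over idx[lo, hi); returns node id.
int grow(const NumericMatrix& X, const IntegerVector& y,
         std::vector<int>& idx, int lo, int hi,
         int mtry, int min_node, int depth, Tree& T,
         std::vector<int>& featPool,
         std::vector<std::pair<double, int> >& buf) {
  const int m = hi - lo;
  int npos = 0;
  for (int t = lo; t < hi; ++t) npos += y[idx[t]];

  int node = (int)T.feature.size();
  T.feature.push_back(-1);
  T.threshold.push_back(0.0);
  T.left.push_back(-1);
  T.right.push_back(-1);
  T.pred.push_back((double)npos / m);

  if (npos == 0 || npos == m || m < min_node || depth >= MAX_DEPTH)
    return node;

  // candidate features: partial Fisher-Yates over the pool
  const int p = (int)featPool.size();
  int ntry = std::min(mtry, p);
  for (int i = 0; i < ntry; ++i) {
    int j = i + randInt(p - i);
    std::swap(featPool[i], featPool[j]);
  }

  double parentGini = 2.0 * npos * (double)(m - npos) / m;  // m * gini
  double bestGain = EPS;
  int bestF = -1;
  double bestThr = 0.0;

  for (int i = 0; i < ntry; ++i) {
    int f = featPool[i];
    buf.resize(m);
    for (int t = 0; t < m; ++t)
      buf[t] = std::make_pair(X(idx[lo + t], f), y[idx[lo + t]]);
    std::sort(buf.begin(), buf.end());
    int lp = 0;  // positives left of the split
    for (int t = 1; t < m; ++t) {
      lp += buf[t - 1].second;
      if (buf[t].first <= buf[t - 1].first + EPS) continue;
      double ln = t, rn = m - t;
      double childGini = 2.0 * lp * (ln - lp) / ln +
                         2.0 * (npos - lp) * (rn - (npos - lp)) / rn;
      double gain = parentGini - childGini;
      if (gain > bestGain) {
        bestGain = gain;
        bestF = f;
        bestThr = 0.5 * (buf[t - 1].first + buf[t].first);
      }
    }
  }
  if (bestF < 0) return node;

  // partition idx[lo,hi) on the chosen split
  int mid = lo;
  for (int t = lo; t < hi; ++t)
    if (X(idx[t], bestF) <= bestThr) std::swap(idx[t], idx[mid++]);
  if (mid == lo || mid == hi) return node;  // degenerate (ties)

  T.feature[node] = bestF;
  T.threshold[node] = bestThr;
  int l = grow(X, y, idx, lo, mid, mtry, min_node, depth + 1, T, featPool, buf);
  int r = grow(X, y, idx, mid, hi, mtry, min_node, depth + 1, T, featPool, buf);
  T.left[node] = l;
  T.right[node] = r;
  return node;
}

double treeScore(const IntegerVector& feature, const NumericVector& threshold,
                 const IntegerVector& left, const IntegerVector& right,
                 const NumericVector& pred, const NumericMatrix& X, int row) {
  int node = 0;
  while (feature[node] >= 0)
    node = (X(row, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
  return pred[node];
}

}  // namespace

// [[Rcpp::export(name = ".rfTrainCpp")]]
List rfTrainCpp(NumericMatrix X, IntegerVector y, int nTrees, int mtry,
                int minNode) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 2) stop("need at least 2 samples to train a forest");
  List trees(nTrees);
  std::vector<int> featPool(p), idx(n);
  std::vector<std::pair<double, int> > buf;
  for (int b = 0; b < nTrees; ++b) {
    for (int i = 0; i < p; ++i) featPool[i] = i;
    for (int i = 0; i < n; ++i) idx[i] = randInt(n);  // bootstrap
    Tree T;
    grow(X, y, idx, 0, n, mtry, minNode, 0, T, featPool, buf);
    trees[b] = List::create(
        _["feature"] = wrap(T.feature), _["threshold"] = wrap(T.threshold),
        _["left"] = wrap(T.left), _["right"] = wrap(T.right),
        _["pred"] = wrap(T.pred));
  }
  return trees;
}

// [[Rcpp::export(name = ".rfPredictCpp")]]
NumericVector rfPredictCpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), B = trees.size();
  NumericVector out(n);
  for (int b = 0; b < B; ++b) {
    List t = trees[b];
    IntegerVector feature = t["feature"], left = t["left"], right = t["right"];
    NumericVector threshold = t["threshold"], pred = t["pred"];
    for (int i = 0; i < n; ++i)
      out[i] += treeScore(feature, threshold, left, right, pred, X, i);
  }
  return out / (double)B;
}
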