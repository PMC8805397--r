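#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Flat CART regression tree grown by variance (SSE) reduction.
// Serves both the probability random forest (y in {0,1}, leaf = class
// fraction) and the gradient-boosting stages (y = pseudo-residuals).
// Nodes are stored in parallel arrays; feature == -1 marks a leaf.

struct TreeNodes {
  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> value;   // mean response in node
  std::vector<double> cover;   // number of training rows reaching node
};

static void grow(const NumericMatrix& X, const NumericVector& y,
                 std::vector<int>& idx, int lo, int hi, int depth,
                 int max_depth, int min_node, int mtry,
                 std::mt19937& rng, TreeNodes& T) {
  int n = hi - lo;
  double sum = 0.0, sum2 = 0.0;
  for (int k = lo; k < hi; ++k) { double v = y[idx[k]]; sum += v; sum2 += v * v; }
  double mean = sum / n;
  double sse = sum2 - sum * sum / n;

  int node = (int)T.feature.size();
  T.feature.push_back(-1); T.threshold.push_back(0.0);
  T.left.push_back(-1); T.right.push_back(-1);
  T.value.push_back(mean); T.cover.push_back((double)n);

  if (depth >= max_depth || n < 2 * min_node || sse <= 1e-12) return;

  int p = X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  if (mtry < p) {               // per-node feature subsampling
    for (int j = 0; j < mtry; ++j) {
      std::uniform_int_distribution<int> U(j, p - 1);
      std::swap(feats[j], feats[U(rng)]);
    }
    feats.resize(mtry);
  }

  double best_gain = 1e-12; int best_f = -1; double best_thr = 0.0;
  std::vector<std::pair<double, int> > vals(n);
  for (size_t fi = 0; fi < feats.size(); ++fi) {
    int f = feats[fi];
    for (int k = 0; k < n; ++k) vals[k] = std::make_pair(X(idx[lo + k], f), idx[lo + k]);
    std::sort(vals.begin(), vals.end());
    double lsum = 0.0, lsum2 = 0.0;
    for (int k = 0; k < n - 1; ++k) {
      double v = y[vals[k].second];
      lsum += v; lsum2 += v * v;
      if (vals[k].first == vals[k + 1].first) continue;
      int nl = k + 1, nr = n - nl;
      if (nl < min_node || nr < min_node) continue;
      double rsum = sum - lsum, rsum2 = sum2 - lsum2;
      double sse_l = lsum2 - lsum * lsum / nl;
      double sse_r = rsum2 - rsum * rsum / nr;
      double gain = sse - sse_l - sse_r;
      if (gain > best_gain) {
        best_gain = gain; best_f = f;
        best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
      }
    }
  }
  if (best_f < 0) return;

  // partition idx[lo,hi) in place
  int mid = lo;
  for (int k = lo; k < hi; ++k)
    if (X(idx[k], best_f) <= best_thr) std::swap(idx[k], idx[mid++]);
  if (mid == lo || mid == hi) return;   // numeric guard

  T.feature[node] = best_f; T.threshold[node] = best_thr;
  T.left[node] = (int)T.feature.size();
  grow(X, y, idx, lo, mid, depth + 1, max_depth, min_node, mtry, rng, T);
  T.right[node] = (int)T.feature.size();
  grow(X, y, idx, mid, hi, depth + 1, max_depth, min_node, mtry, rng, T);
}

// [[Rcpp::export]]
List cart_build(NumericMatrix X, NumericVector y, IntegerVector rows,
                int max_depth, int min_node, int mtry, int seed) {
  std::mt19937 rng((unsigned)seed);
  std::vector<int> idx(rows.size());
  for (int k = 0; k < rows.size(); ++k) idx[k] = rows[k];
  TreeNodes T;
  grow(X, y, idx, 0, (int)idx.size(), 0, max_depth, min_node, mtry, rng, T);
  return List::create(_["feature"] = wrap(T.feature),
                      _["threshold"] = wrap(T.threshold),
                      _["left"] = wrap(T.left),
                      _["right"] = wrap(T.right),
                      _["value"] = wrap(T.value),
                      _["cover"] = wrap(T.cover));
}

static int descend(const IntegerVector& feature, const NumericVector& threshold,
                   const IntegerVector& left, const IntegerVector& right,
                   const NumericMatrix& X, int i) {
  int node = 0;
  while (feature[node] >= 0)
    node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
  return node;
}

// [[Rcpp::export]]
NumericVector cart_predict(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"], right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = value[descend(feature, threshold, left, right, X, i)];
  return out;
}

// [[Rcpp::export]]
IntegerVector cart_leaf_id(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"], right = tree["right"];
  NumericVector threshold = tree["threshold"];
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = descend(feature, threshold, left, right, X, i);
  return out;
}
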