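#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Weighted binary CART with the gini criterion.  Supports depth limits,
// minimum node sizes, and per-node random feature subsampling (mtry) so the
// same grower backs single trees, bagged forests, and boosting stumps.
// Feature subsampling consumes R's RNG stream, so fits are reproducible
// under set.seed().

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold;
  int left, right;  // child indices, -1 for leaf
  double p0, p1;    // weighted class proportions at the node
  int n;            // unweighted sample count
};

inline double gini2(double w0, double w1) {
  double W = w0 + w1;
  if (W <= 0) return 0.0;
  return 2.0 * (w0 / W) * (w1 / W);
}

struct Grower {
  const NumericMatrix &X;
  const IntegerVector &y;
  const NumericVector &w;
  int max_depth, min_split, min_leaf, mtry;
  double total_w;
  std::vector<Node> nodes;
  std::vector<double> importance;
  std::vector<int> feat_pool;

  Grower(const NumericMatrix &X_, const IntegerVector &y_,
         const NumericVector &w_, int max_depth_, int min_split_,
         int min_leaf_, int mtry_)
      : X(X_), y(y_), w(w_), max_depth(max_depth_), min_split(min_split_),
        min_leaf(min_leaf_), mtry(mtry_) {
    importance.assign(X.ncol(), 0.0);
    feat_pool.resize(X.ncol());
    for (int j = 0; j < X.ncol(); ++j) feat_pool[j] = j;
    total_w = 0.0;
    for (int i = 0; i < (int)w_.size(); ++i) total_w += w_[i];
  }

  // partial Fisher-Yates using R's RNG; leaves the chosen m in front
  void sample_features(int m) {
    int p = feat_pool.size();
    for (int i = 0; i < m; ++i) {
      int j = i + (int)(unif_rand() * (p - i));
      if (j >= p) j = p - 1;
      std::swap(feat_pool[i], feat_pool[j]);
    }
  }

  int grow(std::vector<int> &idx, int depth) {
    double w0 = 0.0, w1 = 0.0;
    for (int i : idx) { if (y[i] == 0) w0 += w[i]; else w1 += w[i]; }
    double W = w0 + w1;
    int id = nodes.size();
    nodes.push_back(Node{-1, 0.0, -1, -1, w0 / W, w1 / W, (int)idx.size()});

    bool stop = (w0 == 0.0 || w1 == 0.0) ||
                ((int)idx.size() < min_split) ||
                (max_depth >= 0 && depth >= max_depth);
    if (stop) return id;

    double parent_imp = gini2(w0, w1);
    int m = (mtry > 0 && mtry < (int)feat_pool.size()) ? mtry
                                                       : (int)feat_pool.size();
    // features are always visited in random order and a split must be
    // strictly better to displace the incumbent, so exact ties between
    // equally separating features are broken uniformly at random rather
    // than by column order (reference-implementation behaviour)
    sample_features(m);

    int best_f = -1;
    double best_thr = 0.0, best_gain = 1e-12;
    int n = idx.size();
    std::vector<std::pair<double, int>> vals(n);

    for (int fi = 0; fi < m; ++fi) {
      int f = feat_pool[fi];
      for (int k = 0; k < n; ++k) vals[k] = {X(idx[k], f), idx[k]};
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      double lw0 = 0.0, lw1 = 0.0;
      for (int k = 0; k < n - 1; ++k) {
        int i = vals[k].second;
        if (y[i] == 0) lw0 += w[i]; else lw1 += w[i];
        if (vals[k + 1].first <= vals[k].first) continue;
        int nl = k + 1, nr = n - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        double rw0 = w0 - lw0, rw1 = w1 - lw1;
        double lW = lw0 + lw1, rW = rw0 + rw1;
        double gain = parent_imp - (lW / W) * gini2(lw0, lw1)
                                 - (rW / W) * gini2(rw0, rw1);
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
        }
      }
    }

    if (best_f < 0) return id;

    std::vector<int> li, ri;
    li.reserve(n); ri.reserve(n);
    for (int i : idx)
      (X(i, best_f) <= best_thr ? li : ri).push_back(i);
    if (li.empty() || ri.empty()) return id;

    importance[best_f] += (W / total_w) * best_gain;
    std::vector<int>().swap(idx);  // free before recursing
    int l = grow(li, depth + 1);
    int r = grow(ri, depth + 1);
    nodes[id].feature = best_f;
    nodes[id].threshold = best_thr;
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }
};

} // namespace

// [[Rcpp::export(name = ".cart_fit")]]
List cart_fit(NumericMatrix X, IntegerVector y, NumericVector w,
              int max_depth, int min_split, int min_leaf, int mtry) {
  RNGScope scope;
  Grower g(X, y, w, max_depth, min_split, min_leaf, mtry);
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  g.grow(idx, 0);

  int nn = g.nodes.size();
  IntegerVector feature(nn), left(nn), right(nn), nvec(nn);
  NumericVector thr(nn), p0(nn), p1(nn);
  for (int i = 0; i < nn; ++i) {
    feature[i] = g.nodes[i].feature;
    thr[i] = g.nodes[i].threshold;
    left[i] = g.nodes[i].left;
    right[i] = g.nodes[i].right;
    p0[i] = g.nodes[i].p0;
    p1[i] = g.nodes[i].p1;
    nvec[i] = g.nodes[i].n;
  }
  NumericVector imp(wrap(g.importance));
  double s = sum(imp);
  if (s > 0) imp = imp / s;
  return List::create(_["feature"] = feature, _["threshold"] = thr,
                      _["left"] = left, _["right"] = right, _["p0"] = p0,
                      _["p1"] = p1, _["n"] = nvec, _["importance"] = imp);
}

// [[Rcpp::export(name = ".cart_predict")]]
NumericMatrix cart_predict(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector thr = tree["threshold"], p0 = tree["p0"], p1 = tree["p1"];
  int n = X.nrow();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0)
      node = (X(i, feature[node]) <= thr[node]) ? left[node] : right[node];
    out(i, 0) = p0[node];
    out(i, 1) = p1[node];
  }
  return out;
}
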