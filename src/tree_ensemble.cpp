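// Regression-tree ensemble with variance-reduction (impurity-decrease)
// feature importance, the compute core of the network-inference module.
//
// Importance of a feature in one tree = sum over nodes split on it of the
// decrease in residual sum of squares:
//   dSSE = Sl^2/Nl + Sr^2/Nr - S^2/N   (S = sum of y in node)
// Ensemble importance = mean of the per-tree totals. Splits are exhaustive
// over midpoints between distinct feature values ("rf" mode) or drawn
// uniformly within the node's feature range ("extra-trees" mode).
//
// Determinism: a std::mt19937 seeded per call drives bootstrap and feature
// subsampling; callers canonicalise sample order before entry.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

struct SplitResult {
  int feature = -1;
  double threshold = 0.0;
  double reduction = 0.0;
};

// draw k distinct values from 0..n-1 (partial Fisher-Yates)
static std::vector<int> sample_features(int n, int k, std::mt19937 &rng) {
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  for (int i = 0; i < k; ++i) {
    int j = i + static_cast<int>(rng() % static_cast<uint32_t>(n - i));
    std::swap(idx[i], idx[j]);
  }
  idx.resize(k);
  return idx;
}

class TreeBuilder {
public:
  TreeBuilder(const NumericMatrix &X, const NumericVector &y,
              int mtry, int min_node, int max_depth, bool extra_trees,
              std::mt19937 &rng, std::vector<double> &importance,
              SplitResult &root_split)
      : X_(X), y_(y), mtry_(mtry), min_node_(min_node),
        max_depth_(max_depth), extra_(extra_trees), rng_(rng),
        importance_(importance), root_(root_split) {}

  void build(std::vector<int> &idx) { grow(idx, 0); }

private:
  const NumericMatrix &X_;
  const NumericVector &y_;
  int mtry_, min_node_, max_depth_;
  bool extra_;
  std::mt19937 &rng_;
  std::vector<double> &importance_;
  SplitResult &root_;

  SplitResult best_split(const std::vector<int> &idx,
                         const std::vector<int> &feats) const {
    const int n = static_cast<int>(idx.size());
    double S = 0.0;
    for (int i : idx) S += y_[i];
    SplitResult best;

    std::vector<std::pair<double, int>> vals(n);
    for (int f : feats) {
      for (int i = 0; i < n; ++i)
        vals[i] = std::make_pair(X_(idx[i], f), idx[i]);
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;  // constant

      if (!extra_) {
        double Sl = 0.0;
        for (int i = 0; i < n - 1; ++i) {
          Sl += y_[vals[i].second];
          if (vals[i].first == vals[i + 1].first) continue;  // not a boundary
          const int nl = i + 1, nr = n - nl;
          if (nl < min_node_ || nr < min_node_) continue;
          const double Sr = S - Sl;
          const double red = Sl * Sl / nl + Sr * Sr / nr - S * S / n;
          if (red > best.reduction + 1e-12 ||
              (best.feature < 0 && red > 1e-12)) {
            best.feature = f;
            best.threshold = 0.5 * (vals[i].first + vals[i + 1].first);
            best.reduction = red;
          }
        }
      } else {
        const double lo = vals.front().first, hi = vals.back().first;
        std::uniform_real_distribution<double> unif(lo, hi);
        const double thr = unif(rng_);
        double Sl = 0.0;
        int nl = 0;
        for (int i = 0; i < n; ++i) {
          if (vals[i].first <= thr) { Sl += y_[vals[i].second]; ++nl; }
        }
        const int nr = n - nl;
        if (nl < min_node_ || nr < min_node_) continue;
        const double Sr = S - Sl;
        const double red = Sl * Sl / nl + Sr * Sr / nr - S * S / n;
        if (red > best.reduction + 1e-12 || (best.feature < 0 && red > 1e-12)) {
          best.feature = f;
          best.threshold = thr;
          best.reduction = red;
        }
      }
    }
    return best;
  }

  void grow(std::vector<int> &idx, int depth) {
    const int n = static_cast<int>(idx.size());
    if (n < 2 * min_node_) return;
    if (max_depth_ > 0 && depth >= max_depth_) return;

    const int p = X_.ncol();
    std::vector<int> feats = (mtry_ >= p)
        ? [&] { std::vector<int> all(p); for (int i = 0; i < p; ++i) all[i] = i; return all; }()
        : sample_features(p, mtry_, rng_);

    SplitResult sp = best_split(idx, feats);
    if (sp.feature < 0 || sp.reduction <= 1e-12) return;

    importance_[sp.feature] += sp.reduction;
    if (depth == 0) root_ = sp;

    std::vector<int> left, right;
    left.reserve(n);
    right.reserve(n);
    for (int i : idx)
      (X_(i, sp.feature) <= sp.threshold ? left : right).push_back(i);
    grow(left, depth + 1);
    grow(right, depth + 1);
  }
};

}  // namespace

// [[Rcpp::export(name = ".tree_ensemble_importance")]]
List tree_ensemble_importance(NumericMatrix X, NumericVector y,
                              int n_trees, int mtry, int min_node,
                              int max_depth, bool bootstrap,
                              bool extra_trees, int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("X and y disagree on sample count");
  if (n_trees < 1) stop("n_trees must be >= 1");
  if (mtry < 1) mtry = 1;
  if (min_node < 1) min_node = 1;

  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::vector<double> importance(p, 0.0);
  IntegerVector root_feature(n_trees, NA_INTEGER);
  NumericVector root_threshold(n_trees, NA_REAL);
  NumericVector root_reduction(n_trees, NA_REAL);

  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i)
        idx[i] = static_cast<int>(rng() % static_cast<uint32_t>(n));
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    SplitResult root;
    TreeBuilder builder(X, y, mtry, min_node, max_depth, extra_trees, rng,
                        importance, root);
    builder.build(idx);
    if (root.feature >= 0) {
      root_feature[t] = root.feature + 1;  // 1-based for R
      root_threshold[t] = root.threshold;
      root_reduction[t] = root.reduction;
    }
  }

  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = importance[j] / n_trees;

  return List::create(_["importance"] = imp,
                      _["root_feature"] = root_feature,
                      _["root_threshold"] = root_threshold,
                      _["root_reduction"] = root_reduction);
}
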