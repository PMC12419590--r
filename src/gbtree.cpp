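// Gradient-boosted regression trees, squared-error loss.
//
// Depth-wise exact-greedy CART with an XGBoost-style split gain
//   gain = GL^2/(nL+lambda) + GR^2/(nR+lambda) - G^2/(n+lambda)
// and shrunk leaf values G/(n+lambda). For squared error the gradient of
// sample i is simply its current residual, so G is a residual sum.
//
// Trees are returned as plain numeric matrices (one row per node, columns
// feature/threshold/left/right/value with 0-based child indices, feature = -1
// marking leaves) so that a fitted model is an ordinary R list: serializable,
// inspectable, and independent of this translation unit's memory layout.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;     // -1 => leaf
  double threshold = 0; // go left when x < threshold
  int left = -1, right = -1;
  double value = 0;     // leaf prediction (already shrunk)
  int depth = 0;
};

struct SplitCand {
  double gain = 0;
  int feature = -1;
  double threshold = 0;
  bool found = false;
};

// One depth-wise level pass: for every active node find its best split by
// scanning each feature in globally pre-sorted order.
class TreeBuilder {
public:
  TreeBuilder(const NumericMatrix& X,
              const std::vector<std::vector<int> >& order,
              int max_depth, int min_split, int min_leaf, double lambda)
    : X_(X), order_(order), max_depth_(max_depth), min_split_(min_split),
      min_leaf_(min_leaf), lambda_(lambda) {}

  // residual: gradient targets; in_sample: row subset used for this tree
  std::vector<Node> build(const std::vector<double>& residual,
                          const std::vector<char>& in_sample) {
    const int n = X_.nrow(), p = X_.ncol();
    std::vector<Node> nodes;
    std::vector<int> node_of(n, -1);
    double G = 0; int cnt = 0;
    for (int i = 0; i < n; ++i)
      if (in_sample[i]) { node_of[i] = 0; G += residual[i]; ++cnt; }
    Node root; root.depth = 0; root.value = G / (cnt + lambda_);
    nodes.push_back(root);
    std::vector<int> active(1, 0);
    std::vector<double> node_G(1, G);
    std::vector<int> node_n(1, cnt);

    for (int depth = 0; depth < max_depth_ && !active.empty(); ++depth) {
      const int m = (int) nodes.size();
      std::vector<char> is_active(m, 0);
      for (int id : active)
        if (node_n[id] >= min_split_) is_active[id] = 1;

      std::vector<SplitCand> best(m);
      std::vector<double> GL(m), prev(m);
      std::vector<int> nL(m);
      std::vector<char> seen(m);

      for (int j = 0; j < p; ++j) {
        std::fill(GL.begin(), GL.end(), 0.0);
        std::fill(nL.begin(), nL.end(), 0);
        std::fill(seen.begin(), seen.end(), 0);
        const std::vector<int>& ord = order_[j];
        for (int k = 0; k < n; ++k) {
          const int i = ord[k];
          const int nd = node_of[i];
          if (nd < 0 || !is_active[nd]) continue;
          const double x = X_(i, j);
          if (seen[nd] && x > prev[nd] &&
              nL[nd] >= min_leaf_ && node_n[nd] - nL[nd] >= min_leaf_) {
            const double gl = GL[nd], gr = node_G[nd] - gl;
            const int cl = nL[nd], cr = node_n[nd] - cl;
            const double gain = gl * gl / (cl + lambda_) +
                                gr * gr / (cr + lambda_) -
                                node_G[nd] * node_G[nd] / (node_n[nd] + lambda_);
            SplitCand& b = best[nd];
            if (!b.found || gain > b.gain + 1e-12) {
              b.found = true; b.gain = gain; b.feature = j;
              b.threshold = prev[nd] + (x - prev[nd]) / 2.0;
            }
          }
          GL[nd] += residual[i];
          ++nL[nd];
          prev[nd] = x;
          seen[nd] = 1;
        }
      }

      // materialize children, reassign samples
      std::vector<int> next_active;
      for (int id : active) {
        if (!is_active[id] || !best[id].found || best[id].gain <= 1e-12) continue;
        nodes[id].feature = best[id].feature;
        nodes[id].threshold = best[id].threshold;
        Node l, r; l.depth = r.depth = nodes[id].depth + 1;
        const int left = (int) nodes.size();
        nodes.push_back(l);
        nodes.push_back(r);
        nodes[id].left = left;
        nodes[id].right = left + 1;
        node_G.resize(nodes.size(), 0.0);
        node_n.resize(nodes.size(), 0);
        next_active.push_back(left);
        next_active.push_back(left + 1);
      }
      if (next_active.empty()) break;
      for (int i = 0; i < n; ++i) {
        int nd = node_of[i];
        if (nd < 0 || nodes[nd].feature < 0) continue;
        const Node& cur = nodes[nd];
        const int child = X_(i, cur.feature) < cur.threshold ? cur.left : cur.right;
        node_of[i] = child;
        node_G[child] += residual[i];
        node_n[child] += 1;
      }
      for (int id : next_active)
        nodes[id].value = node_G[id] / (node_n[id] + lambda_);
      active.swap(next_active);
    }
    return nodes;
  }

private:
  const NumericMatrix& X_;
  const std::vector<std::vector<int> >& order_;
  int max_depth_, min_split_, min_leaf_;
  double lambda_;
};

NumericMatrix pack(const std::vector<Node>& nodes) {
  NumericMatrix out((int) nodes.size(), 5);
  colnames(out) = CharacterVector::create("feature", "threshold",
                                          "left", "right", "value");
  for (size_t i = 0; i < nodes.size(); ++i) {
    out(i, 0) = nodes[i].feature;
    out(i, 1) = nodes[i].threshold;
    out(i, 2) = nodes[i].left;
    out(i, 3) = nodes[i].right;
    out(i, 4) = nodes[i].value;
  }
  return out;
}

double predict_one(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    const int j = (int) tree(node, 0);
    node = X(row, j) < tree(node, 1) ? (int) tree(node, 2) : (int) tree(node, 3);
  }
  return tree(node, 4);
}

// Deterministic 64-bit mix for the optional row subsampling; avoids touching
// R's global RNG stream from compiled code.
inline std::uint64_t splitmix64(std::uint64_t& s) {
  s += 0x9e3779b97f4a7c15ULL;
  std::uint64_t z = s;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

std::vector<std::vector<int> > presort(const NumericMatrix& X) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<std::vector<int> > order(p);
  for (int j = 0; j < p; ++j) {
    order[j].resize(n);
    for (int i = 0; i < n; ++i) order[j][i] = i;
    const int jj = j;
    std::stable_sort(order[j].begin(), order[j].end(),
                     [&X, jj](int a, int b) { return X(a, jj) < X(b, jj); });
  }
  return order;
}

} // namespace

// [[Rcpp::export(name = ".gbt_fit_cpp")]]
List gbt_fit_cpp(NumericMatrix X, NumericVector y,
                 int n_estimators, int max_depth, double learning_rate,
                 int min_split, int min_leaf, double lambda,
                 double subsample, int seed) {
  const int n = X.nrow();
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  if (n_estimators < 1) stop("n_estimators must be >= 1");
  const std::vector<std::vector<int> > order = presort(X);
  TreeBuilder builder(X, order, max_depth, min_split, min_leaf, lambda);

  const double init = mean(y);
  std::vector<double> pred(n, init), residual(n);
  std::vector<char> in_sample(n, 1);
  std::uint64_t rng_state = (std::uint64_t) seed * 2654435761ULL + 1ULL;
  List trees(n_estimators);

  for (int t = 0; t < n_estimators; ++t) {
    if (subsample < 1.0) {
      for (int i = 0; i < n; ++i) {
        const double u = (splitmix64(rng_state) >> 11) * 0x1.0p-53;
        in_sample[i] = u < subsample ? 1 : 0;
      }
    }
    for (int i = 0; i < n; ++i) residual[i] = y[i] - pred[i];
    std::vector<Node> nodes = builder.build(residual, in_sample);
    NumericMatrix tree = pack(nodes);
    for (int i = 0; i < n; ++i)
      pred[i] += learning_rate * predict_one(tree, X, i);
    trees[t] = tree;
  }
  return List::create(_["init"] = init, _["trees"] = trees,
                      _["learning_rate"] = learning_rate);
}

// [[Rcpp::export(name = ".gbt_predict_cpp")]]
NumericVector gbt_predict_cpp(List model, NumericMatrix X) {
  const int n = X.nrow();
  const double init = as<double>(model["init"]);
  const double lr = as<double>(model["learning_rate"]);
  List trees = model["trees"];
  NumericVector out(n, init);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i)
      out[i] += lr * predict_one(tree, X, i);
  }
  return out;
}

// [[Rcpp::export(name = ".tree_fit_cpp")]]
NumericMatrix tree_fit_cpp(NumericMatrix X, NumericVector y,
                           int max_depth, int min_split, int min_leaf,
                           double lambda) {
  const std::vector<std::vector<int> > order = presort(X);
  TreeBuilder builder(X, order, max_depth, min_split, min_leaf, lambda);
  std::vector<double> residual(y.begin(), y.end());
  std::vector<char> in_sample(X.nrow(), 1);
  return pack(builder.build(residual, in_sample));
}

// [[Rcpp::export(name = ".tree_predict_cpp")]]
NumericVector tree_predict_cpp(NumericMatrix tree, NumericMatrix X) {
  NumericVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) out[i] = predict_one(tree, X, i);
  return out;
}
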