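// Seeded binary-classification random forest (CART / Gini), self-contained so
// the package has no dependency on randomForest/ranger. Determinism contract:
// identical (X, y, hyperparameters, seed) => identical forest, importance and
// predictions. RNG is a private mt19937, independent of R's RNG state.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold;
  int left, right;  // child indices
  double prob1;     // class-1 probability (leaf payload)
};

struct Tree {
  std::vector<Node> nodes;
};

struct SplitResult {
  int feature = -1;
  double threshold = 0.0;
  double decrease = 0.0;  // impurity decrease, node-size weighted
};

inline double gini(double n1, double n) {
  if (n <= 0.0) return 0.0;
  double p = n1 / n;
  return 2.0 * p * (1.0 - p);
}

class ForestBuilder {
public:
  ForestBuilder(const NumericMatrix& X, const IntegerVector& y,
                int mtry, int min_node, int max_depth, std::mt19937& rng)
      : X_(X), y_(y), mtry_(mtry), min_node_(min_node),
        max_depth_(max_depth), rng_(rng), p_((int)X.ncol()),
        importance_(X.ncol(), 0.0) {}

  Tree grow(const std::vector<int>& sample_idx) {
    Tree t;
    build(t, sample_idx, 0);
    return t;
  }

  std::vector<double> importance_;

private:
  const NumericMatrix& X_;
  const IntegerVector& y_;
  int mtry_, min_node_, max_depth_;
  std::mt19937& rng_;
  int p_;
  std::vector<int> feat_pool_;

  int build(Tree& t, const std::vector<int>& idx, int depth) {
    int me = (int)t.nodes.size();
    t.nodes.push_back(Node{-1, 0.0, -1, -1, 0.0});
    double n = (double)idx.size(), n1 = 0.0;
    for (int i : idx) n1 += y_[i];
    t.nodes[me].prob1 = n > 0 ? n1 / n : 0.5;

    if (n1 == 0.0 || n1 == n || (int)idx.size() < 2 * min_node_ ||
        depth >= max_depth_)
      return me;

    SplitResult best = best_split(idx, n, n1);
    if (best.feature < 0) return me;

    std::vector<int> li, ri;
    li.reserve(idx.size()); ri.reserve(idx.size());
    for (int i : idx) {
      if (X_(i, best.feature) <= best.threshold) li.push_back(i);
      else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) return me;

    importance_[best.feature] += best.decrease;
    t.nodes[me].feature = best.feature;
    t.nodes[me].threshold = best.threshold;
    int l = build(t, li, depth + 1);
    int r = build(t, ri, depth + 1);
    t.nodes[me].left = l;
    t.nodes[me].right = r;
    return me;
  }

  SplitResult best_split(const std::vector<int>& idx, double n, double n1) {
    if ((int)feat_pool_.size() != p_) {
      feat_pool_.resize(p_);
      for (int j = 0; j < p_; ++j) feat_pool_[j] = j;
    }
    // partial Fisher-Yates: first mtry_ entries are the sampled features
    int m = std::min(mtry_, p_);
    for (int j = 0; j < m; ++j) {
      std::uniform_int_distribution<int> d(j, p_ - 1);
      std::swap(feat_pool_[j], feat_pool_[d(rng_)]);
    }
    double g0 = gini(n1, n);
    SplitResult best;
    std::vector<std::pair<double, int>> vals;
    vals.reserve(idx.size());
    for (int jj = 0; jj < m; ++jj) {
      int f = feat_pool_[jj];
      vals.clear();
      for (int i : idx) vals.emplace_back(X_(i, f), y_[i]);
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      double ln = 0.0, ln1 = 0.0;
      for (size_t k = 0; k + 1 < vals.size(); ++k) {
        ln += 1.0; ln1 += vals[k].second;
        if (vals[k].first == vals[k + 1].first) continue;
        if (ln < min_node_ || (n - ln) < min_node_) continue;
        double dec = g0 - (ln / n) * gini(ln1, ln)
                        - ((n - ln) / n) * gini(n1 - ln1, n - ln);
        if (dec > best.decrease + 1e-15) {
          best.decrease = dec;
          best.feature = f;
          best.threshold = 0.5 * (vals[k].first + vals[k + 1].first);
        }
      }
    }
    if (best.feature >= 0) best.decrease *= n;  // weight by node size
    return best;
  }
};

double predict_tree(const Tree& t, const NumericMatrix& X, int row) {
  int cur = 0;
  while (t.nodes[cur].feature >= 0) {
    cur = (X(row, t.nodes[cur].feature) <= t.nodes[cur].threshold)
              ? t.nodes[cur].left : t.nodes[cur].right;
  }
  return t.nodes[cur].prob1;
}

List tree_to_list(const Tree& t) {
  int k = (int)t.nodes.size();
  IntegerVector feature(k), left(k), right(k);
  NumericVector threshold(k), prob1(k);
  for (int i = 0; i < k; ++i) {
    feature[i] = t.nodes[i].feature;
    threshold[i] = t.nodes[i].threshold;
    left[i] = t.nodes[i].left;
    right[i] = t.nodes[i].right;
    prob1[i] = t.nodes[i].prob1;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["prob1"] = prob1);
}

Tree tree_from_list(const List& l) {
  IntegerVector feature = l["feature"], left = l["left"], right = l["right"];
  NumericVector threshold = l["threshold"], prob1 = l["prob1"];
  Tree t;
  t.nodes.resize(feature.size());
  for (int i = 0; i < feature.size(); ++i)
    t.nodes[i] = Node{feature[i], threshold[i], left[i], right[i], prob1[i]};
  return t;
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                int min_node, int max_depth, int seed) {
  int n = X.nrow();
  std::mt19937 rng((unsigned)seed);
  ForestBuilder fb(X, y, mtry, min_node, max_depth, rng);
  List trees(n_trees);
  std::uniform_int_distribution<int> pick(0, n - 1);
  for (int b = 0; b < n_trees; ++b) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = pick(rng);
    std::sort(idx.begin(), idx.end());
    trees[b] = tree_to_list(fb.grow(idx));
  }
  NumericVector imp(X.ncol());
  double denom = (double)n * n_trees;
  for (int j = 0; j < X.ncol(); ++j) imp[j] = fb.importance_[j] / denom;
  return List::create(_["trees"] = trees, _["importance"] = imp);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  List trees = forest["trees"];
  int n = X.nrow(), B = trees.size();
  NumericVector out(n);
  for (int b = 0; b < B; ++b) {
    Tree t = tree_from_list(trees[b]);
    for (int i = 0; i < n; ++i) out[i] += predict_tree(t, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= B;
  return out;
}
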