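// Random forest core: CART trees grown on bootstrap resamples with per-node
// feature subsampling. Classification trees split on Gini impurity and
// predict by majority vote across trees; regression trees split on variance
// reduction and predict by averaging. Uses R's RNG so results are
// reproducible via set.seed() in the calling R code.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for a leaf
  double threshold; // go left when x <= threshold
  int left, right;  // child node ids
  double value;     // class index (classification) or mean (regression)
};

struct BuildJob {
  int node_id;
  int lo, hi; // segment of the index vector owned by this node
};

// Draw `k` distinct integers from 0..n-1 (partial Fisher-Yates, R RNG).
void sample_features(std::vector<int> &pool, int k, std::vector<int> &out) {
  int n = (int)pool.size();
  out.clear();
  for (int i = 0; i < k; ++i) {
    int j = i + (int)(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(pool[i], pool[j]);
    out.push_back(pool[i]);
  }
}

class TreeBuilder {
public:
  TreeBuilder(const NumericMatrix &X, const NumericVector &y, int n_classes,
              int mtry, int min_node)
      : X_(X), y_(y), n_classes_(n_classes), mtry_(mtry), min_node_(min_node),
        p_(X.ncol()) {
    for (int j = 0; j < p_; ++j) feature_pool_.push_back(j);
  }

  // Grow one tree on the rows in `idx` (bootstrap indices, with repeats).
  std::vector<Node> grow(std::vector<int> &idx) {
    nodes_.clear();
    std::vector<BuildJob> stack;
    nodes_.push_back(Node());
    stack.push_back(BuildJob{0, 0, (int)idx.size()});
    std::vector<int> feats;
    while (!stack.empty()) {
      BuildJob job = stack.back();
      stack.pop_back();
      int n = job.hi - job.lo;
      double leaf_value = node_value(idx, job.lo, job.hi);
      bool stop = (n < 2 * min_node_) || is_pure(idx, job.lo, job.hi);
      int best_feat = -1;
      double best_thr = 0.0, best_score = R_PosInf;
      if (!stop) {
        sample_features(feature_pool_, std::min(mtry_, p_), feats);
        for (size_t f = 0; f < feats.size(); ++f)
          consider_feature(idx, job.lo, job.hi, feats[f], best_feat, best_thr,
                           best_score);
      }
      if (best_feat < 0) {
        nodes_[job.node_id] =
            Node{-1, 0.0, -1, -1, leaf_value};
        continue;
      }
      // stable partition: rows with x <= thr go left
      std::stable_partition(idx.begin() + job.lo, idx.begin() + job.hi,
                            [&](int i) { return X_(i, best_feat) <= best_thr; });
      int mid = job.lo;
      while (mid < job.hi && X_(idx[mid], best_feat) <= best_thr) ++mid;
      int left_id = (int)nodes_.size();
      nodes_.push_back(Node());
      int right_id = (int)nodes_.size();
      nodes_.push_back(Node());
      nodes_[job.node_id] = Node{best_feat, best_thr, left_id, right_id, 0.0};
      stack.push_back(BuildJob{left_id, job.lo, mid});
      stack.push_back(BuildJob{right_id, mid, job.hi});
    }
    return nodes_;
  }

private:
  const NumericMatrix &X_;
  const NumericVector &y_;
  int n_classes_; // 0 => regression
  int mtry_, min_node_, p_;
  std::vector<int> feature_pool_;
  std::vector<Node> nodes_;
  std::vector<std::pair<double, double>> buf_; // (x value, y value)

  bool is_pure(const std::vector<int> &idx, int lo, int hi) const {
    double y0 = y_[idx[lo]];
    for (int i = lo + 1; i < hi; ++i)
      if (y_[idx[i]] != y0) return false;
    return true;
  }

  double node_value(const std::vector<int> &idx, int lo, int hi) const {
    if (n_classes_ > 0) {
      std::vector<int> counts(n_classes_, 0);
      for (int i = lo; i < hi; ++i) counts[(int)y_[idx[i]]]++;
      int best = 0;
      for (int c = 1; c < n_classes_; ++c)
        if (counts[c] > counts[best]) best = c; // ties -> lowest class index
      return (double)best;
    }
    double s = 0.0;
    for (int i = lo; i < hi; ++i) s += y_[idx[i]];
    return s / (hi - lo);
  }

  // Scan all midpoints of feature `f`; lower `best_score` wins.
  void consider_feature(const std::vector<int> &idx, int lo, int hi, int f,
                        int &best_feat, double &best_thr, double &best_score) {
    int n = hi - lo;
    buf_.clear();
    for (int i = lo; i < hi; ++i)
      buf_.push_back(std::make_pair(X_(idx[i], f), y_[idx[i]]));
    std::sort(buf_.begin(), buf_.end());
    if (buf_.front().first == buf_.back().first) return; // constant feature
    if (n_classes_ > 0) {
      std::vector<int> left(n_classes_, 0), total(n_classes_, 0);
      for (int i = 0; i < n; ++i) total[(int)buf_[i].second]++;
      for (int i = 0; i < n - 1; ++i) {
        left[(int)buf_[i].second]++;
        if (buf_[i].first == buf_[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        if (nl < min_node_ || nr < min_node_) continue;
        double gl = 0.0, gr = 0.0;
        for (int c = 0; c < n_classes_; ++c) {
          double pl = (double)left[c] / nl;
          double pr = (double)(total[c] - left[c]) / nr;
          gl += pl * pl;
          gr += pr * pr;
        }
        // weighted Gini impurity of the children
        double score = nl * (1.0 - gl) + nr * (1.0 - gr);
        if (score < best_score) {
          best_score = score;
          best_feat = f;
          best_thr = 0.5 * (buf_[i].first + buf_[i + 1].first);
        }
      }
    } else {
      double sum_r = 0.0, sumsq_r = 0.0;
      for (int i = 0; i < n; ++i) {
        sum_r += buf_[i].second;
        sumsq_r += buf_[i].second * buf_[i].second;
      }
      double sum_l = 0.0, sumsq_l = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        double yv = buf_[i].second;
        sum_l += yv;
        sumsq_l += yv * yv;
        if (buf_[i].first == buf_[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        if (nl < min_node_ || nr < min_node_) continue;
        double sse_l = sumsq_l - sum_l * sum_l / nl;
        double sum_rr = sum_r - sum_l, sumsq_rr = sumsq_r - sumsq_l;
        double sse_rr = sumsq_rr - sum_rr * sum_rr / nr;
        double score = sse_l + sse_rr;
        if (score < best_score) {
          best_score = score;
          best_feat = f;
          best_thr = 0.5 * (buf_[i].first + buf_[i + 1].first);
        }
      }
    }
  }
};

NumericMatrix pack_tree(const std::vector<Node> &nodes) {
  NumericMatrix m(nodes.size(), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    m(i, 0) = nodes[i].feature;
    m(i, 1) = nodes[i].threshold;
    m(i, 2) = nodes[i].left;
    m(i, 3) = nodes[i].right;
    m(i, 4) = nodes[i].value;
  }
  return m;
}

double predict_tree(const NumericMatrix &tree, const NumericMatrix &X, int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    int f = (int)tree(node, 0);
    node = (X(row, f) <= tree(node, 1)) ? (int)tree(node, 2) : (int)tree(node, 3);
  }
  return tree(node, 4);
}

} // namespace

// [[Rcpp::export]]
List cpp_rf_fit(NumericMatrix X, NumericVector y, int n_classes, int n_trees,
                int mtry, int min_node) {
  RNGScope scope;
  int n = X.nrow();
  TreeBuilder builder(X, y, n_classes, mtry, min_node);
  List trees(n_trees);
  std::vector<int> idx(n);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) {
      int j = (int)(unif_rand() * n);
      idx[i] = (j >= n) ? n - 1 : j;
    }
    trees[t] = pack_tree(builder.grow(idx));
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector cpp_rf_predict(List trees, NumericMatrix X, int n_classes) {
  int n = X.nrow(), n_trees = trees.size();
  NumericVector out(n);
  if (n_classes > 0) {
    std::vector<int> votes(n_classes);
    for (int i = 0; i < n; ++i) {
      std::fill(votes.begin(), votes.end(), 0);
      for (int t = 0; t < n_trees; ++t) {
        NumericMatrix tree = trees[t];
        votes[(int)predict_tree(tree, X, i)]++;
      }
      int best = 0;
      for (int c = 1; c < n_classes; ++c)
        if (votes[c] > votes[best]) best = c; // ties -> lowest class index
      out[i] = best;
    }
  } else {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int t = 0; t < n_trees; ++t) {
        NumericMatrix tree = trees[t];
        s += predict_tree(tree, X, i);
      }
      out[i] = s / n_trees;
    }
  }
  return out;
}
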