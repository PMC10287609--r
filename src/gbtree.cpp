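// Second-order gradient-boosted decision trees for binary classification
// (logistic loss), exact greedy split search. Kept deliberately small:
// dense feature matrix, L2 leaf regularization, no column/row subsampling.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Node {
  int feature = -1;        // -1 = leaf
  double threshold = 0.0;  // go left when x <= threshold
  int left = -1, right = -1;
  double value = 0.0;      // leaf weight
};

struct BuildCtx {
  const NumericMatrix& X;
  const std::vector<double>& g;
  const std::vector<double>& h;
  double lambda;
  double min_child_weight;
  int max_depth;
  std::vector<Node> nodes;
  BuildCtx(const NumericMatrix& X_, const std::vector<double>& g_,
           const std::vector<double>& h_, double lambda_, double mcw_,
           int depth_)
      : X(X_), g(g_), h(h_), lambda(lambda_), min_child_weight(mcw_),
        max_depth(depth_) {}
};

static int build_node(BuildCtx& ctx, std::vector<int>& idx, int depth) {
  double G = 0.0, H = 0.0;
  for (int i : idx) { G += ctx.g[i]; H += ctx.h[i]; }
  Node node;
  node.value = -G / (H + ctx.lambda);

  double best_gain = 1e-12;
  int best_feat = -1;
  double best_thr = 0.0;
  const double parent_score = G * G / (H + ctx.lambda);

  if (depth < ctx.max_depth && idx.size() >= 2) {
    const int p = ctx.X.ncol();
    std::vector<int> ord;
    for (int j = 0; j < p; ++j) {
      ord = idx;
      const int jj = j;
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return ctx.X(a, jj) < ctx.X(b, jj);
      });
      double GL = 0.0, HL = 0.0;
      for (size_t k = 0; k + 1 < ord.size(); ++k) {
        GL += ctx.g[ord[k]];
        HL += ctx.h[ord[k]];
        double x_here = ctx.X(ord[k], jj), x_next = ctx.X(ord[k + 1], jj);
        if (x_here == x_next) continue;
        double HR = H - HL;
        if (HL < ctx.min_child_weight || HR < ctx.min_child_weight) continue;
        double GR = G - GL;
        double gain = GL * GL / (HL + ctx.lambda) +
                      GR * GR / (HR + ctx.lambda) - parent_score;
        if (gain > best_gain) {
          best_gain = gain;
          best_feat = jj;
          best_thr = 0.5 * (x_here + x_next);
        }
      }
    }
  }

  int my_id = (int)ctx.nodes.size();
  ctx.nodes.push_back(node);
  if (best_feat >= 0) {
    std::vector<int> lidx, ridx;
    for (int i : idx) {
      if (ctx.X(i, best_feat) <= best_thr) lidx.push_back(i);
      else ridx.push_back(i);
    }
    if (!lidx.empty() && !ridx.empty()) {
      ctx.nodes[my_id].feature = best_feat;
      ctx.nodes[my_id].threshold = best_thr;
      int l = build_node(ctx, lidx, depth + 1);
      int r = build_node(ctx, ridx, depth + 1);
      ctx.nodes[my_id].left = l;
      ctx.nodes[my_id].right = r;
    }
  }
  return my_id;
}

static double tree_predict_row(const std::vector<Node>& nodes,
                               const NumericMatrix& X, int row) {
  int cur = 0;
  while (nodes[cur].feature >= 0) {
    cur = (X(row, nodes[cur].feature) <= nodes[cur].threshold)
              ? nodes[cur].left
              : nodes[cur].right;
  }
  return nodes[cur].value;
}

static List tree_to_list(const std::vector<Node>& nodes) {
  int n = (int)nodes.size();
  IntegerVector feature(n), left(n), right(n);
  NumericVector threshold(n), value(n);
  for (int i = 0; i < n; ++i) {
    feature[i] = nodes[i].feature;
    threshold[i] = nodes[i].threshold;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    value[i] = nodes[i].value;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["value"] = value);
}

static std::vector<Node> tree_from_list(const List& tl) {
  IntegerVector feature = tl["feature"], left = tl["left"],
                right = tl["right"];
  NumericVector threshold = tl["threshold"], value = tl["value"];
  std::vector<Node> nodes(feature.size());
  for (int i = 0; i < feature.size(); ++i) {
    nodes[i].feature = feature[i];
    nodes[i].threshold = threshold[i];
    nodes[i].left = left[i];
    nodes[i].right = right[i];
    nodes[i].value = value[i];
  }
  return nodes;
}

// [[Rcpp::export(name = ".gbt_fit_cpp")]]
List gbt_fit_cpp(NumericMatrix X, NumericVector y, int nrounds, double eta,
                 int max_depth, double lambda, double min_child_weight) {
  const int n = X.nrow();
  double ybar = (double)mean(y);
  ybar = std::min(std::max(ybar, 1e-6), 1.0 - 1e-6);
  double base = std::log(ybar / (1.0 - ybar));
  std::vector<double> margin(n, base), g(n), h(n);
  List trees(nrounds);
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  for (int round = 0; round < nrounds; ++round) {
    for (int i = 0; i < n; ++i) {
      double p = 1.0 / (1.0 + std::exp(-margin[i]));
      g[i] = p - y[i];
      h[i] = std::max(p * (1.0 - p), 1e-12);
    }
    BuildCtx ctx(X, g, h, lambda, min_child_weight, max_depth);
    std::vector<int> idx = all;
    build_node(ctx, idx, 0);
    for (int i = 0; i < n; ++i) {
      margin[i] += eta * tree_predict_row(ctx.nodes, X, i);
    }
    trees[round] = tree_to_list(ctx.nodes);
  }
  return List::create(_["base_score"] = base, _["eta"] = eta,
                      _["trees"] = trees);
}

// [[Rcpp::export(name = ".gbt_margin_cpp")]]
NumericVector gbt_margin_cpp(List model, NumericMatrix X) {
  const int n = X.nrow();
  double base = as<double>(model["base_score"]);
  double eta = as<double>(model["eta"]);
  List trees = model["trees"];
  NumericVector out(n, base);
  for (int t = 0; t < trees.size(); ++t) {
    std::vector<Node> nodes = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) {
      out[i] += eta * tree_predict_row(nodes, X, i);
    }
  }
  return out;
}
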