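#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Regression forest on a single predictor (injection order). mtry is
// trivially 1; trees are grown on bootstrap resamples until the node
// size falls to `nodesize`. Splits minimize within-node SSE over
// midpoints of adjacent distinct x values.

struct Node {
  double thresh;   // split threshold; NA for leaf
  double value;    // leaf mean
  int left, right; // child indices, -1 for leaf
};

static int grow(std::vector<Node> &tree, const std::vector<double> &x,
                const std::vector<double> &y, std::vector<int> idx,
                int nodesize) {
  int id = (int)tree.size();
  tree.push_back(Node());
  double sum = 0.0;
  for (int i : idx) sum += y[i];
  int n = (int)idx.size();
  tree[id].value = sum / n;
  tree[id].thresh = NA_REAL;
  tree[id].left = tree[id].right = -1;
  if (n <= nodesize) return id;

  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  // prefix sums for SSE deltas
  double best_gain = 0.0, best_thresh = NA_REAL;
  int best_cut = -1;
  double total = sum, left_sum = 0.0;
  for (int cut = 0; cut < n - 1; ++cut) {
    left_sum += y[idx[cut]];
    if (x[idx[cut]] == x[idx[cut + 1]]) continue;
    int nl = cut + 1, nr = n - nl;
    double right_sum = total - left_sum;
    double gain = left_sum * left_sum / nl + right_sum * right_sum / nr -
                  total * total / n;
    if (gain > best_gain + 1e-12) {
      best_gain = gain;
      best_cut = cut;
      best_thresh = 0.5 * (x[idx[cut]] + x[idx[cut + 1]]);
    }
  }
  if (best_cut < 0) return id;
  std::vector<int> li(idx.begin(), idx.begin() + best_cut + 1);
  std::vector<int> ri(idx.begin() + best_cut + 1, idx.end());
  tree[id].thresh = best_thresh;
  int l = grow(tree, x, y, li, nodesize);
  int r = grow(tree, x, y, ri, nodesize);
  tree[id].left = l;
  tree[id].right = r;
  return id;
}

static double tree_predict(const std::vector<Node> &tree, double x0) {
  int cur = 0;
  while (tree[cur].left >= 0)
    cur = (x0 <= tree[cur].thresh) ? tree[cur].left : tree[cur].right;
  return tree[cur].value;
}

// [[Rcpp::export]]
NumericVector rf1d_predict_cpp(NumericVector x, NumericVector y,
                               NumericVector xout, int ntree, int nodesize,
                               int seed) {
  int n = x.size(), m = xout.size();
  std::vector<double> xs(x.begin(), x.end()), ys(y.begin(), y.end());
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> pick(0, n - 1);
  NumericVector pred(m, 0.0);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = pick(rng);
    std::vector<Node> tree;
    grow(tree, xs, ys, idx, nodesize);
    for (int j = 0; j < m; ++j) pred[j] += tree_predict(tree, xout[j]);
  }
  for (int j = 0; j < m; ++j) pred[j] /= ntree;
  return pred;
}
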