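// Hill-climbing structure learning for Gaussian Bayesian networks under
// the BIC score, plus the bootstrap model-averaging loop. Operates on
// the MLE covariance matrix; local score of node v with parent set P is
//   -n/2 (log(2 pi s2) + 1) - (|P| + 2)/2 log n,
// s2 the conditional variance from the Schur complement. Search starts
// from the empty graph with add/remove/reverse operators, in-degree
// capped at max_parents; candidate order is shuffled by the seed so ties
// are broken reproducibly but without a fixed variable-order bias.
#include <RcppArmadillo.h>
#include <random>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static double local_score(const mat &C, double n, int v,
                          const std::vector<int> &parents) {
  double s2;
  int k = (int)parents.size();
  if (k == 0) {
    s2 = C(v, v);
  } else {
    uvec P(k);
    for (int i = 0; i < k; ++i) P[i] = parents[i];
    mat Cpp = C.submat(P, P);
    // tiny ridge keeps collinear parent sets (e.g. exact linear
    // relations in a bootstrap resample) finite and warning-free
    Cpp.diag() += 1e-10;
    vec cvp = C.submat(P, uvec{(unsigned)v});
    vec b = solve(Cpp, cvp, solve_opts::fast + solve_opts::likely_sympd);
    s2 = C(v, v) - dot(cvp, b);
  }
  if (s2 < 1e-12) s2 = 1e-12;
  return -0.5 * n * (std::log(2.0 * M_PI * s2) + 1.0) -
         0.5 * (k + 2) * std::log(n);
}

struct HC {
  int p;
  double n;
  int maxp;
  const mat &C;
  umat adj;                 // adj(u,v) = 1 iff edge u -> v
  std::vector<std::vector<int>> parents;
  vec cur;                  // current local score per node
  mat dAdd, dRem;           // deltas for add(u,v), remove(u,v)

  HC(const mat &C_, double n_, int maxp_)
      : p(C_.n_cols), n(n_), maxp(maxp_), C(C_), adj(p, p, fill::zeros),
        parents(p), cur(p), dAdd(p, p, fill::zeros), dRem(p, p, fill::zeros) {
    for (int v = 0; v < p; ++v) cur[v] = local_score(C, n, v, parents[v]);
    for (int v = 0; v < p; ++v) refresh_col(v);
  }

  void refresh_col(int v) {
    for (int u = 0; u < p; ++u) {
      if (u == v) continue;
      if (adj(u, v)) {
        std::vector<int> P;
        for (int w : parents[v]) if (w != u) P.push_back(w);
        dRem(u, v) = local_score(C, n, v, P) - cur[v];
      } else if (!adj(v, u)) {
        std::vector<int> P(parents[v]);
        P.push_back(u);
        dAdd(u, v) = local_score(C, n, v, P) - cur[v];
      }
    }
  }

  // scratch buffers for cycle checks (reused across iterations)
  std::vector<char> seen_buf;
  std::vector<int> stack_buf;

  // is `to` reachable from `from`, optionally ignoring edge (skipu,skipv)
  bool reaches(int from, int to, int skipu = -1, int skipv = -1) {
    if (from == to) return true;
    seen_buf.assign(p, 0);
    stack_buf.clear();
    stack_buf.push_back(from);
    seen_buf[from] = 1;
    while (!stack_buf.empty()) {
      int u = stack_buf.back();
      stack_buf.pop_back();
      for (int v = 0; v < p; ++v) {
        if (!adj(u, v) || seen_buf[v]) continue;
        if (u == skipu && v == skipv) continue;
        if (v == to) return true;
        seen_buf[v] = 1;
        stack_buf.push_back(v);
      }
    }
    return false;
  }

  // full descendant closure: reach[u*p+v] = 1 iff v reachable from u
  void closure(std::vector<char> &reach) {
    reach.assign((size_t)p * p, 0);
    for (int s = 0; s < p; ++s) {
      stack_buf.clear();
      stack_buf.push_back(s);
      char *row = &reach[(size_t)s * p];
      row[s] = 1;
      while (!stack_buf.empty()) {
        int u = stack_buf.back();
        stack_buf.pop_back();
        for (int v = 0; v < p; ++v)
          if (adj(u, v) && !row[v]) {
            row[v] = 1;
            stack_buf.push_back(v);
          }
      }
    }
  }

  void apply_add(int u, int v) {
    adj(u, v) = 1;
    parents[v].push_back(u);
    cur[v] = local_score(C, n, v, parents[v]);
    refresh_col(v);
    refresh_col(u); // add(v,u) entries become invalid / valid flips
  }
  void apply_rem(int u, int v) {
    adj(u, v) = 0;
    auto &P = parents[v];
    P.erase(std::find(P.begin(), P.end(), u));
    cur[v] = local_score(C, n, v, P);
    refresh_col(v);
    refresh_col(u);
  }

  void run(std::mt19937 &rng) {
    std::vector<std::pair<int, int>> pairs;
    pairs.reserve(p * (p - 1));
    for (int u = 0; u < p; ++u)
      for (int v = 0; v < p; ++v)
        if (u != v) pairs.emplace_back(u, v);
    std::shuffle(pairs.begin(), pairs.end(), rng);
    const double eps = 1e-6;
    std::vector<char> reach;
    for (int iter = 0; iter < 100 * p; ++iter) {
      closure(reach);
      double best = eps;
      int op = -1, bu = -1, bv = -1;
      for (auto &pr : pairs) {
        int u = pr.first, v = pr.second;
        if (adj(u, v)) {
          double d = dRem(u, v);
          if (d > best) { best = d; op = 1; bu = u; bv = v; }
          // reverse u->v : remove + add v->u; cheap score screen before
          // the (more expensive) acyclicity check
          if ((int)parents[u].size() < maxp) {
            std::vector<int> P(parents[u]);
            P.push_back(v);
            double d2 = dRem(u, v) + local_score(C, n, u, P) - cur[u];
            if (d2 > best && !reaches(u, v, u, v)) {
              best = d2; op = 2; bu = u; bv = v;
            }
          }
        } else if (!adj(v, u)) {
          if ((int)parents[v].size() >= maxp) continue;
          if (reach[(size_t)v * p + u]) continue; // would close a cycle
          double d = dAdd(u, v);
          if (d > best) { best = d; op = 0; bu = u; bv = v; }
        }
      }
      if (op < 0) break;
      if (op == 0) apply_add(bu, bv);
      else if (op == 1) apply_rem(bu, bv);
      else { apply_rem(bu, bv); apply_add(bv, bu); }
    }
  }
};

static mat cov_of(const mat &X) {
  mat Xc = X.each_row() - mean(X, 0);
  return (Xc.t() * Xc) / X.n_rows;
}

// [[Rcpp::export]]
arma::umat hc_cpp(const arma::mat &X, int max_parents, int seed) {
  std::mt19937 rng((unsigned)seed);
  mat C = cov_of(X);
  HC hc(C, (double)X.n_rows, max_parents);
  hc.run(rng);
  return hc.adj;
}

// [[Rcpp::export]]
arma::mat hc_bootstrap_cpp(const arma::mat &X, const arma::imat &idx,
                           int max_parents, int seed) {
  int p = X.n_cols, B = idx.n_cols;
  std::mt19937 rng((unsigned)seed);
  mat counts(p, p, fill::zeros);
  for (int b = 0; b < B; ++b) {
    mat Xb(idx.n_rows, p);
    for (unsigned i = 0; i < idx.n_rows; ++i)
      Xb.row(i) = X.row(idx(i, b) - 1);
    mat C = cov_of(Xb);
    HC hc(C, (double)Xb.n_rows, max_parents);
    hc.run(rng);
    // skeleton: direction discarded
    for (int u = 0; u < p; ++u)
      for (int v = u + 1; v < p; ++v)
        if (hc.adj(u, v) || hc.adj(v, u)) {
          counts(u, v) += 1.0;
          counts(v, u) += 1.0;
        }
  }
  return counts / B;
}
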