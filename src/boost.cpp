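// Weighted stochastic gradient boosting for Bernoulli loss, with
// best-first regression-tree base learners and an exact weighted
// tree-traversal partial dependence routine.
//
// Tree storage: one numeric matrix per tree, one row per node, columns
//   0 var   : 0-based predictor index of the split, -1 for a terminal node
//   1 split : split value; rows with x < split go left, x >= split go right
//   2 left  : row index of left child (-1 for terminal)
//   3 right : row index of right child
//   4 gain  : weighted least-squares improvement of the split (0 at leaves)
//   5 value : terminal logit increment, already scaled by the learning rate
#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct SplitInfo {
  int var;
  double split;
  double gain;
  bool found;
};

struct NodeRec {
  std::vector<int> rows;   // indices into the bag
  int depth;
  SplitInfo best;
  int mat_row;             // row in the output tree matrix
  bool expanded;
};

// Best weighted-LS split of `rows` (indices into bag arrays) for one tree.
// Residual targets r, weights w. min_obs applies to raw counts on each side.
SplitInfo best_split(const NumericMatrix& X, const std::vector<int>& bag,
                     const std::vector<double>& r, const std::vector<double>& w,
                     const std::vector<int>& rows, int min_obs) {
  SplitInfo best;
  best.found = false;
  best.gain = 1e-10;   // gains below this are floating noise around zero
  best.var = -1;
  best.split = 0.0;
  const int m = (int)rows.size();
  if (m < 2 * min_obs) return best;

  double sw = 0.0, swr = 0.0;
  for (int i = 0; i < m; ++i) { sw += w[rows[i]]; swr += w[rows[i]] * r[rows[i]]; }
  const double parent = (sw > 0.0) ? swr * swr / sw : 0.0;

  std::vector<int> ord(rows);
  std::vector<double> xv(m);
  const int p = X.ncol();
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < m; ++i) xv[i] = X(bag[rows[i]], j);
    // sort row ids of this node by predictor j
    std::vector<int> idx(m);
    for (int i = 0; i < m; ++i) idx[i] = i;
    std::stable_sort(idx.begin(), idx.end(),
                     [&](int a, int b) { return xv[a] < xv[b]; });
    double swl = 0.0, swrl = 0.0;
    int cl = 0;
    for (int i = 0; i < m - 1; ++i) {
      const int ri = rows[idx[i]];
      swl += w[ri];
      swrl += w[ri] * r[ri];
      ++cl;
      const double x_here = xv[idx[i]], x_next = xv[idx[i + 1]];
      if (x_here >= x_next) continue;        // no boundary between ties
      if (cl < min_obs || (m - cl) < min_obs) continue;
      const double swr_ = sw - swl, swrr = swr - swrl;
      double gain = 0.0;
      if (swl > 0.0) gain += swrl * swrl / swl;
      if (swr_ > 0.0) gain += swrr * swrr / swr_;
      gain -= parent;
      if (gain > best.gain) {               // strict >: first (lowest var,
        best.gain = gain;                   // lowest split) candidate wins ties
        best.var = j;
        best.split = 0.5 * (x_here + x_next);
        best.found = true;
      }
    }
  }
  if (!best.found) best.gain = 0.0;
  return best;
}

inline double clamp_prob(double p) {
  if (p < 1e-12) return 1e-12;
  if (p > 1.0 - 1e-12) return 1.0 - 1e-12;
  return p;
}

} // namespace

// Fit `n_trees` boosting iterations, continuing from per-row logit state F.
// Weights w are expected pre-normalized to mean 1 by the caller. Bagging
// draws floor(bag_fraction*n) rows without replacement via R's RNG (no RNG
// is consumed when bag_fraction == 1). Returns the trees, the updated F and
// the per-iteration weighted training deviance (-2*sum(w*ll)/sum(w)).
// [[Rcpp::export]]
List cpp_boost(NumericMatrix X, NumericVector y, NumericVector w,
               NumericVector F, double learning_rate, int tree_depth,
               int max_leaves, int min_obs, double bag_fraction, int n_trees) {
  const int n = X.nrow();
  NumericVector Fout = clone(F);
  List trees(n_trees);
  NumericVector train_dev(n_trees);
  double sw_all = 0.0;
  for (int i = 0; i < n; ++i) sw_all += w[i];

  const int m_bag = (bag_fraction >= 1.0) ? n
      : std::max(1, (int)std::floor(bag_fraction * n));

  std::vector<double> prob(n), resid(n);
  std::vector<int> bag(n);

  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) {
      prob[i] = 1.0 / (1.0 + std::exp(-Fout[i]));
    }
    // bag selection
    std::vector<int> the_bag;
    if (m_bag == n) {
      the_bag.resize(n);
      for (int i = 0; i < n; ++i) the_bag[i] = i;
    } else {
      IntegerVector draw = Rcpp::sample(n, m_bag, false);  // 1-based, R RNG
      the_bag.resize(m_bag);
      for (int i = 0; i < m_bag; ++i) the_bag[i] = draw[i] - 1;
    }
    const int m = (int)the_bag.size();
    std::vector<double> r(m), wb(m), pb(m);
    for (int i = 0; i < m; ++i) {
      const int gi = the_bag[i];
      r[i] = y[gi] - prob[gi];
      wb[i] = w[gi];
      pb[i] = prob[gi];
    }

    // ---- grow one tree, best-first by gain ----
    std::vector<NodeRec> nodes;
    {
      NodeRec root;
      root.rows.resize(m);
      for (int i = 0; i < m; ++i) root.rows[i] = i;
      root.depth = 0;
      root.best = (tree_depth > 0)
          ? best_split(X, the_bag, r, wb, root.rows, min_obs)
          : SplitInfo{-1, 0.0, 0.0, false};
      root.mat_row = -1;
      root.expanded = false;
      nodes.push_back(root);
    }
    int n_leaves = 1;
    while (n_leaves < max_leaves) {
      int pick = -1;
      double gbest = 0.0;
      for (size_t k = 0; k < nodes.size(); ++k) {
        if (!nodes[k].expanded && nodes[k].best.found &&
            nodes[k].best.gain > gbest) {
          gbest = nodes[k].best.gain;
          pick = (int)k;
        }
      }
      if (pick < 0) break;
      nodes[pick].expanded = true;
      NodeRec lc, rc;
      lc.depth = rc.depth = nodes[pick].depth + 1;
      lc.mat_row = rc.mat_row = -1;
      lc.expanded = rc.expanded = false;
      for (size_t ii = 0; ii < nodes[pick].rows.size(); ++ii) {
        const int ri = nodes[pick].rows[ii];
        if (X(the_bag[ri], nodes[pick].best.var) < nodes[pick].best.split)
          lc.rows.push_back(ri);
        else
          rc.rows.push_back(ri);
      }
      lc.best = (lc.depth < tree_depth)
          ? best_split(X, the_bag, r, wb, lc.rows, min_obs)
          : SplitInfo{-1, 0.0, 0.0, false};
      rc.best = (rc.depth < tree_depth)
          ? best_split(X, the_bag, r, wb, rc.rows, min_obs)
          : SplitInfo{-1, 0.0, 0.0, false};
      nodes.push_back(lc);                   // may reallocate: index, not ref
      const int lid = (int)nodes.size() - 1;
      nodes.push_back(rc);
      const int rid = (int)nodes.size() - 1;
      nodes[pick].rows.clear();
      nodes[pick].rows.push_back(-lid - 1);  // negative-coded child ids
      nodes[pick].rows.push_back(-rid - 1);
      ++n_leaves;
    }

    // ---- emit matrix (preorder over the node vector) ----
    const int n_nodes = (int)nodes.size();
    NumericMatrix tree(n_nodes, 6);
    // map node id -> matrix row (identity works: nodes vector order is stable)
    for (int k = 0; k < n_nodes; ++k) {
      const NodeRec& nd = nodes[k];
      const bool internal = nd.expanded;
      if (internal) {
        const int lid = -(int)nd.rows[0] - 1;
        const int rid = -(int)nd.rows[1] - 1;
        tree(k, 0) = nd.best.var;
        tree(k, 1) = nd.best.split;
        tree(k, 2) = lid;
        tree(k, 3) = rid;
        tree(k, 4) = nd.best.gain;
        tree(k, 5) = 0.0;
      } else {
        double swr = 0.0, shess = 0.0;
        for (size_t ii = 0; ii < nd.rows.size(); ++ii) {
          const int ri = nd.rows[ii];
          swr += wb[ri] * r[ri];
          shess += wb[ri] * pb[ri] * (1.0 - pb[ri]);
        }
        const double value = swr / (shess + 1e-6);  // weighted Newton step
        tree(k, 0) = -1;
        tree(k, 1) = 0.0;
        tree(k, 2) = -1;
        tree(k, 3) = -1;
        tree(k, 4) = 0.0;
        tree(k, 5) = learning_rate * value;
      }
    }

    // ---- update F on all rows ----
    for (int i = 0; i < n; ++i) {
      int k = 0;
      while (tree(k, 0) >= 0) {
        k = (X(i, (int)tree(k, 0)) < tree(k, 1)) ? (int)tree(k, 2)
                                                 : (int)tree(k, 3);
      }
      Fout[i] += tree(k, 5);
    }
    trees[t] = tree;

    double dev = 0.0;
    for (int i = 0; i < n; ++i) {
      const double p = clamp_prob(1.0 / (1.0 + std::exp(-Fout[i])));
      dev += w[i] * (y[i] * std::log(p) + (1.0 - y[i]) * std::log(1.0 - p));
    }
    train_dev[t] = -2.0 * dev / sw_all;
  }

  return List::create(_["trees"] = trees, _["F"] = Fout,
                      _["train_deviance"] = train_dev);
}

// Sum of tree increments (logit scale) for the first n_use trees.
// [[Rcpp::export]]
NumericVector cpp_predict_trees(List trees, NumericMatrix X, int n_use) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int t = 0; t < n_use; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) {
      int k = 0;
      while (tree(k, 0) >= 0) {
        k = (X(i, (int)tree(k, 0)) < tree(k, 1)) ? (int)tree(k, 2)
                                                 : (int)tree(k, 3);
      }
      out[i] += tree(k, 5);
    }
  }
  return out;
}

namespace {

// Exact weighted partial-dependence traversal: recursion partitions the
// training rows at splits on non-target predictors and the grid points at
// splits on target predictors, so each (leaf, grid point) pair receives the
// leaf value weighted by the training mass that reaches the leaf once the
// target predictors are clamped to the grid value. Equivalent to clamping
// and averaging predictions, without materializing clamped copies.
void pd_recurse(const NumericMatrix& tree, int k, const NumericMatrix& X,
                const NumericVector& w, const std::vector<int>& tcols,
                const NumericMatrix& grid, std::vector<int>& rows,
                std::vector<int>& gpts, double w_total, NumericVector& out) {
  const int var = (int)tree(k, 0);
  if (var < 0) {
    double wn = 0.0;
    for (size_t i = 0; i < rows.size(); ++i) wn += w[rows[i]];
    const double contrib = tree(k, 5) * wn / w_total;
    for (size_t g = 0; g < gpts.size(); ++g) out[gpts[g]] += contrib;
    return;
  }
  const double split = tree(k, 1);
  int tpos = -1;
  for (size_t c = 0; c < tcols.size(); ++c)
    if (tcols[c] == var) { tpos = (int)c; break; }
  if (tpos >= 0) {
    std::vector<int> gl, gr;
    for (size_t g = 0; g < gpts.size(); ++g) {
      if (grid(gpts[g], tpos) < split) gl.push_back(gpts[g]);
      else gr.push_back(gpts[g]);
    }
    if (!gl.empty())
      pd_recurse(tree, (int)tree(k, 2), X, w, tcols, grid, rows, gl, w_total, out);
    if (!gr.empty())
      pd_recurse(tree, (int)tree(k, 3), X, w, tcols, grid, rows, gr, w_total, out);
  } else {
    std::vector<int> rl, rr;
    for (size_t i = 0; i < rows.size(); ++i) {
      if (X(rows[i], var) < split) rl.push_back(rows[i]);
      else rr.push_back(rows[i]);
    }
    if (!rl.empty())
      pd_recurse(tree, (int)tree(k, 2), X, w, tcols, grid, rl, gpts, w_total, out);
    if (!rr.empty())
      pd_recurse(tree, (int)tree(k, 3), X, w, tcols, grid, rr, gpts, w_total, out);
  }
}

} // namespace

// Partial dependence on the logit scale (sum over the first n_use trees of
// the weighted traversal); the caller adds the model intercept. `target_cols`
// are 0-based predictor indices (length 1 or 2), `grid` has one column per
// target predictor and one row per evaluation point.
// [[Rcpp::export]]
NumericVector cpp_partial_dependence(List trees, int n_use, NumericMatrix X,
                                     NumericVector w, IntegerVector target_cols,
                                     NumericMatrix grid) {
  const int n = X.nrow();
  const int g = grid.nrow();
  NumericVector out(g);
  double w_total = 0.0;
  for (int i = 0; i < n; ++i) w_total += w[i];
  std::vector<int> tcols(target_cols.begin(), target_cols.end());
  std::vector<int> rows(n), gpts(g);
  for (int i = 0; i < n; ++i) rows[i] = i;
  for (int i = 0; i < g; ++i) gpts[i] = i;
  for (int t = 0; t < n_use; ++t) {
    NumericMatrix tree = trees[t];
    std::vector<int> r0(rows), g0(gpts);
    pd_recurse(tree, 0, X, w, tcols, grid, r0, g0, w_total, out);
  }
  return out;
}
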