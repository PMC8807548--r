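#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

// Gradient-boosted regression trees with second-order (Newton) splits and an
// exact greedy split finder on presorted features. Supports a logistic
// objective (boosting on the log-odds margin) and a "forest" mode in which
// every tree is fit independently to the centered labels and predictions are
// averaged (random-forest style, with row/column subsampling).
//
// Written from the standard GBDT formulation: for node with gradient sum G
// and hessian sum H, leaf weight = -G/(H+lambda); split gain =
// GL^2/(HL+lambda) + GR^2/(HR+lambda) - G^2/(H+lambda).

struct TreeNodes {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> thresh;
  std::vector<int> left, right;
  std::vector<double> value;     // leaf weight (already eta-scaled)
  int add_node() {
    feature.push_back(-1); thresh.push_back(0.0);
    left.push_back(-1); right.push_back(-1); value.push_back(0.0);
    return (int)feature.size() - 1;
  }
};

static inline double boost_sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export]]
List cpp_boost_train(NumericMatrix X, NumericVector y, int nrounds, double eta,
                     int max_depth, double lambda, double min_child_weight,
                     double subsample, double colsample, std::string objective,
                     double seed) {
  const int n = X.nrow(), p = X.ncol();
  Xoshiro256 rng((uint64_t)seed);
  const bool forest = (objective == "forest");

  // presort feature orders once
  std::vector<int> order((size_t)p * n);
  for (int f = 0; f < p; ++f) {
    int* of = &order[(size_t)f * n];
    for (int r = 0; r < n; ++r) of[r] = r;
    const double* col = &X(0, f);
    std::stable_sort(of, of + n, [col](int a, int b) { return col[a] < col[b]; });
  }

  std::vector<double> margin(n, 0.0);   // log-odds for logistic, offset for forest
  std::vector<double> g(n), h(n);
  std::vector<int> pos(n);
  std::vector<int> feats(p);
  for (int f = 0; f < p; ++f) feats[f] = f;
  int n_feats = std::max(1, (int)std::ceil(colsample * p));

  List trees(nrounds);
  const int max_nodes = (1 << (max_depth + 1)) + 1;

  for (int round_i = 0; round_i < nrounds; ++round_i) {
    // gradients
    for (int r = 0; r < n; ++r) {
      if (forest) { g[r] = 0.5 - y[r]; h[r] = 1.0; }
      else {
        double pr = boost_sigmoid(margin[r]);
        g[r] = pr - y[r];
        h[r] = std::max(pr * (1.0 - pr), 1e-16);
      }
    }
    // column subsample (per tree)
    std::vector<int> use_feats;
    if (n_feats < p) {
      std::vector<int> perm(feats);
      for (int i = p - 1; i > 0; --i) std::swap(perm[i], perm[rng.runif_int(i + 1)]);
      use_feats.assign(perm.begin(), perm.begin() + n_feats);
      std::sort(use_feats.begin(), use_feats.end());
    } else use_feats = feats;

    TreeNodes tree;
    int root = tree.add_node();
    for (int r = 0; r < n; ++r)
      pos[r] = (subsample >= 1.0 || rng.runif() < subsample) ? root : -1;

    std::vector<int> active(1, root);
    std::vector<double> Gn(max_nodes, 0.0), Hn(max_nodes, 0.0);
    for (int r = 0; r < n; ++r)
      if (pos[r] >= 0) { Gn[root] += g[r]; Hn[root] += h[r]; }

    std::vector<int> node_slot(max_nodes, -1);
    for (int depth = 0; depth < max_depth && !active.empty(); ++depth) {
      int n_active = (int)active.size();
      for (int s = 0; s < n_active; ++s) node_slot[active[s]] = s;
      std::vector<double> best_gain(n_active, 1e-12), best_thr(n_active, 0.0);
      std::vector<int> best_feat(n_active, -1);
      std::vector<double> GL(n_active), HL(n_active), prev(n_active);
      std::vector<char> seen(n_active);

      for (int fi = 0; fi < (int)use_feats.size(); ++fi) {
        int f = use_feats[fi];
        std::fill(GL.begin(), GL.end(), 0.0);
        std::fill(HL.begin(), HL.end(), 0.0);
        std::fill(seen.begin(), seen.end(), 0);
        const int* of = &order[(size_t)f * n];
        const double* col = &X(0, f);
        for (int idx = 0; idx < n; ++idx) {
          int r = of[idx];
          int nd = pos[r];
          if (nd < 0) continue;
          int s = node_slot[nd];
          if (s < 0) continue;
          double x = col[r];
          if (seen[s] && x > prev[s]) {
            double GR = Gn[nd] - GL[s], HR = Hn[nd] - HL[s];
            if (HL[s] >= min_child_weight && HR >= min_child_weight) {
              double gain = GL[s] * GL[s] / (HL[s] + lambda)
                          + GR * GR / (HR + lambda)
                          - Gn[nd] * Gn[nd] / (Hn[nd] + lambda);
              if (gain > best_gain[s]) {
                best_gain[s] = gain; best_feat[s] = f;
                best_thr[s] = 0.5 * (prev[s] + x);
              }
            }
          }
          GL[s] += g[r]; HL[s] += h[r]; prev[s] = x; seen[s] = 1;
        }
      }

      std::vector<int> next_active;
      std::vector<char> splits_here(n_active, 0);
      for (int s = 0; s < n_active; ++s) {
        int nd = active[s];
        if (best_feat[s] >= 0) {
          int lc = tree.add_node(), rc = tree.add_node();
          tree.feature[nd] = best_feat[s];
          tree.thresh[nd] = best_thr[s];
          tree.left[nd] = lc; tree.right[nd] = rc;
          splits_here[s] = 1;
          next_active.push_back(lc);
          next_active.push_back(rc);
          Gn[lc] = Gn[rc] = Hn[lc] = Hn[rc] = 0.0;
        } else {
          tree.value[nd] = -Gn[nd] / (Hn[nd] + lambda) * (forest ? 1.0 : eta);
        }
      }
      // reassign samples of split nodes
      for (int r = 0; r < n; ++r) {
        int nd = pos[r];
        if (nd < 0) continue;
        int s = node_slot[nd];
        if (s < 0 || !splits_here[s]) continue;
        int child = (X(r, tree.feature[nd]) <= tree.thresh[nd])
                      ? tree.left[nd] : tree.right[nd];
        pos[r] = child;
        Gn[child] += g[r]; Hn[child] += h[r];
      }
      for (int s = 0; s < n_active; ++s) node_slot[active[s]] = -1;
      active = next_active;
    }
    // leaves at max depth
    for (int nd : active)
      tree.value[nd] = -Gn[nd] / (Hn[nd] + lambda) * (forest ? 1.0 : eta);

    // update margins (boosting only)
    int n_nodes = (int)tree.feature.size();
    NumericMatrix tm(n_nodes, 5);
    for (int ndx = 0; ndx < n_nodes; ++ndx) {
      tm(ndx, 0) = tree.feature[ndx]; tm(ndx, 1) = tree.thresh[ndx];
      tm(ndx, 2) = tree.left[ndx]; tm(ndx, 3) = tree.right[ndx];
      tm(ndx, 4) = tree.value[ndx];
    }
    trees[round_i] = tm;
    if (!forest) {
      for (int r = 0; r < n; ++r) {
        int nd = 0;
        while (tree.feature[nd] >= 0)
          nd = (X(r, tree.feature[nd]) <= tree.thresh[nd]) ? tree.left[nd] : tree.right[nd];
        margin[r] += tree.value[nd];
      }
    }
  }
  return List::create(_["trees"] = trees, _["objective"] = objective);
}

// [[Rcpp::export]]
NumericVector cpp_boost_predict(List fit, NumericMatrix X) {
  List trees = fit["trees"];
  std::string objective = as<std::string>(fit["objective"]);
  const bool forest = (objective == "forest");
  const int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tm = trees[t];
    for (int r = 0; r < n; ++r) {
      int nd = 0;
      while (tm(nd, 0) >= 0)
        nd = (X(r, (int)tm(nd, 0)) <= tm(nd, 1)) ? (int)tm(nd, 2) : (int)tm(nd, 3);
      out[r] += tm(nd, 4);
    }
  }
  if (forest) {
    for (int r = 0; r < n; ++r) out[r] = 0.5 + out[r] / T;
    for (int r = 0; r < n; ++r) out[r] = std::min(1.0, std::max(0.0, out[r]));
  } else {
    for (int r = 0; r < n; ++r) out[r] = boost_sigmoid(out[r]);
  }
  return out;
}
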