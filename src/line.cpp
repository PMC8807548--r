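#include <Rcpp.h>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

static inline double sigmoid_clip(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// LINE trainer for one proximity order (1 or 2), edge sampling by the alias
// method proportional to edge weight, negative sampling proportional to
// weighted degree^0.75. Single-threaded; bit-reproducible for a given seed.
//
// src, dst: 0-based directed edge list (undirected graphs pass both
// directions); weight: positive edge weights. One "epoch" draws n_edges
// samples. Learning rate decays linearly to 1e-4 * lr0.
//
// Returns list(u = vertex matrix, uctx = context matrix). For order 1 the
// context table is the vertex table itself and uctx is an empty matrix.
// [[Rcpp::export]]
List cpp_line_train(IntegerVector src, IntegerVector dst, NumericVector weight,
                    int n_nodes, int d, int order, int negative, int epochs,
                    double lr0, double seed) {
  const int n_edges = src.size();
  Xoshiro256 rng((uint64_t)seed);

  AliasTable edge_alias;
  {
    std::vector<double> w(weight.begin(), weight.end());
    edge_alias.build(w);
  }

  // noise distribution over nodes: weighted degree ^ 0.75
  AliasTable noise;
  {
    std::vector<double> deg(n_nodes, 0.0);
    for (int e = 0; e < n_edges; ++e) deg[src[e]] += weight[e];
    for (int i = 0; i < n_nodes; ++i) deg[i] = std::pow(deg[i], 0.75);
    noise.build(deg);
  }

  std::vector<double> u((size_t)n_nodes * d);
  for (size_t i = 0; i < u.size(); ++i)
    u[i] = (rng.runif() - 0.5) / d;
  // order-2 context vectors start at zero, as in word2vec
  std::vector<double> ctx;
  if (order == 2) ctx.assign((size_t)n_nodes * d, 0.0);
  double* tab = (order == 2) ? ctx.data() : u.data();

  const long long total = (long long)epochs * n_edges;
  std::vector<double> grad_i(d);

  for (long long t = 0; t < total; ++t) {
    double lr = lr0 * (1.0 - (double)t / total);
    if (lr < lr0 * 1e-4) lr = lr0 * 1e-4;
    int e = edge_alias.sample(rng);
    int i = src[e], j = dst[e];
    double* ui = &u[(size_t)i * d];
    std::fill(grad_i.begin(), grad_i.end(), 0.0);
    for (int s = 0; s <= negative; ++s) {
      int target; double label;
      if (s == 0) { target = j; label = 1.0; }
      else {
        target = noise.sample(rng);
        if (target == i || target == j) continue;
        label = 0.0;
      }
      double* tv = &tab[(size_t)target * d];
      double dot = 0.0;
      for (int c = 0; c < d; ++c) dot += ui[c] * tv[c];
      double g = (label - sigmoid_clip(dot)) * lr;
      for (int c = 0; c < d; ++c) {
        grad_i[c] += g * tv[c];
        tv[c] += g * ui[c];
      }
    }
    for (int c = 0; c < d; ++c) ui[c] += grad_i[c];
  }

  NumericMatrix um(n_nodes, d);
  for (int i = 0; i < n_nodes; ++i)
    for (int c = 0; c < d; ++c) um(i, c) = u[(size_t)i * d + c];
  NumericMatrix cm(order == 2 ? n_nodes : 0, order == 2 ? d : 0);
  if (order == 2)
    for (int i = 0; i < n_nodes; ++i)
      for (int c = 0; c < d; ++c) cm(i, c) = ctx[(size_t)i * d + c];
  return List::create(_["u"] = um, _["uctx"] = cm);
}
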