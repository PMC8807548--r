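#include <Rcpp.h>
#include <algorithm>
#include "rng.h"

using namespace Rcpp;

// binary search for x in sorted indices[lo, hi)
static inline bool has_edge(const IntegerVector& indices, int lo, int hi, int x) {
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (indices[mid] == x) return true;
    if (indices[mid] < x) lo = mid + 1; else hi = mid;
  }
  return false;
}

// Second-order (node2vec) biased random walks over a CSR adjacency with
// sorted neighbor indices. Bias on step t>1 for candidate x with previous
// node prev: weight * 1/p if x == prev, weight if x ~ prev, weight * 1/q
// otherwise. First step is proportional to edge weight alone.
//
// indptr: length n_nodes+1; indices/weights: CSR neighbor arrays (0-based,
// sorted within each row). Returns an integer matrix with one walk per row
// (n_walks rounds over all start nodes), entries 0-based, -1 past a dead end.
// [[Rcpp::export]]
IntegerMatrix cpp_node2vec_walks(IntegerVector indptr, IntegerVector indices,
                                 NumericVector weights, int n_nodes,
                                 int n_walks, int walk_len,
                                 double p, double q, double seed) {
  Xoshiro256 rng((uint64_t)seed);
  IntegerMatrix walks((R_xlen_t)n_walks * n_nodes, walk_len);
  std::vector<double> cum; // cumulative bias buffer
  int row = 0;
  for (int r = 0; r < n_walks; ++r) {
    for (int start = 0; start < n_nodes; ++start, ++row) {
      int cur = start, prev = -1;
      walks(row, 0) = cur;
      for (int step = 1; step < walk_len; ++step) {
        int lo = indptr[cur], hi = indptr[cur + 1];
        int deg = hi - lo;
        if (deg == 0) { // dead end: pad remainder
          for (int s2 = step; s2 < walk_len; ++s2) walks(row, s2) = -1;
          break;
        }
        cum.resize(deg);
        double acc = 0.0;
        if (prev < 0) {
          for (int k = 0; k < deg; ++k) { acc += weights[lo + k]; cum[k] = acc; }
        } else {
          int plo = indptr[prev], phi = indptr[prev + 1];
          for (int k = 0; k < deg; ++k) {
            int x = indices[lo + k];
            double b;
            if (x == prev) b = 1.0 / p;
            else if (has_edge(indices, plo, phi, x)) b = 1.0;
            else b = 1.0 / q;
            acc += weights[lo + k] * b;
            cum[k] = acc;
          }
        }
        double rdraw = rng.runif() * acc;
        int k = (int)(std::lower_bound(cum.begin(), cum.end(), rdraw) - cum.begin());
        if (k >= deg) k = deg - 1;
        prev = cur;
        cur = indices[lo + k];
        walks(row, step) = cur;
      }
    }
  }
  return walks;
}
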