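#include <Rcpp.h>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

static inline double sgns_sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling over a matrix of walks (one walk per
// row, 0-based node ids, -1 = padding past a dead end). Fixed symmetric
// window; noise distribution proportional to corpus frequency^0.75.
// Single-threaded, bit-reproducible for a given seed.
// [[Rcpp::export]]
NumericMatrix cpp_skipgram_train(IntegerMatrix walks, int n_nodes, int d,
                                 int window, int negative, int epochs,
                                 double lr0, double seed) {
  const int n_walks = walks.nrow(), walk_len = walks.ncol();
  Xoshiro256 rng((uint64_t)seed);

  // contiguous row-major copy of the corpus for the hot loop
  std::vector<int> corpus((size_t)n_walks * walk_len);
  for (int r = 0; r < n_walks; ++r)
    for (int t = 0; t < walk_len; ++t)
      corpus[(size_t)r * walk_len + t] = walks(r, t);

  AliasTable noise;
  {
    std::vector<double> freq(n_nodes, 0.0);
    for (size_t i = 0; i < corpus.size(); ++i)
      if (corpus[i] >= 0) freq[corpus[i]] += 1.0;
    for (int i = 0; i < n_nodes; ++i) freq[i] = std::pow(freq[i], 0.75);
    noise.build(freq);
  }

  std::vector<double> syn0((size_t)n_nodes * d), syn1((size_t)n_nodes * d, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.runif() - 0.5) / d;

  const long long total_centers = (long long)epochs * n_walks * walk_len;
  long long done = 0;
  std::vector<double> grad(d);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int r = 0; r < n_walks; ++r) {
      const int* walk = &corpus[(size_t)r * walk_len];
      for (int t = 0; t < walk_len; ++t, ++done) {
        int center = walk[t];
        if (center < 0) continue;
        double lr = lr0 * (1.0 - (double)done / total_centers);
        if (lr < lr0 * 1e-4) lr = lr0 * 1e-4;
        int c_lo = t - window < 0 ? 0 : t - window;
        int c_hi = t + window >= walk_len ? walk_len - 1 : t + window;
        double* __restrict v = &syn0[(size_t)center * d];
        for (int cpos = c_lo; cpos <= c_hi; ++cpos) {
          if (cpos == t) continue;
          int ctxnode = walk[cpos];
          if (ctxnode < 0) continue;
          double* __restrict gr = grad.data();
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int s = 0; s <= negative; ++s) {
            int target; double label;
            if (s == 0) { target = ctxnode; label = 1.0; }
            else {
              target = noise.sample(rng);
              if (target == ctxnode || target == center) continue;
              label = 0.0;
            }
            double* __restrict w1 = &syn1[(size_t)target * d];
            double dot = 0.0;
            for (int c = 0; c < d; ++c) dot += v[c] * w1[c];
            double g = (label - sgns_sigmoid(dot)) * lr;
            for (int c = 0; c < d; ++c) {
              gr[c] += g * w1[c];
              w1[c] += g * v[c];
            }
          }
          for (int c = 0; c < d; ++c) v[c] += gr[c];
        }
      }
    }
  }

  NumericMatrix out(n_nodes, d);
  for (int i = 0; i < n_nodes; ++i)
    for (int c = 0; c < d; ++c) out(i, c) = syn0[(size_t)i * d + c];
  return out;
}
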