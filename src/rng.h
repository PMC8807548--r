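#ifndef LNCTARGETNET_RNG_H
#define LNCTARGETNET_RNG_H

#include <cstdint>
#include <vector>

// Deterministic, single-threaded RNG independent of R's RNG state so that
// embedding training is bit-reproducible for a given integer seed.
// splitmix64 seeds xoshiro256**.
struct Xoshiro256 {
  uint64_t s[4];

  explicit Xoshiro256(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform double in [0, 1)
  inline double runif() {
    return (next() >> 11) * 0x1.0p-53;
  }

  // uniform integer in [0, n)
  inline int runif_int(int n) {
    return (int)(runif() * n);
  }
};

// Walker alias table for O(1) sampling from a discrete distribution.
struct AliasTable {
  std::vector<double> prob;
  std::vector<int> alias;
  int n;

  AliasTable() : n(0) {}

  void build(const std::vector<double>& w) {
    n = (int)w.size();
    prob.assign(n, 0.0);
    alias.assign(n, 0);
    double total = 0.0;
    for (int i = 0; i < n; ++i) total += w[i];
    std::vector<double> p(n);
    for (int i = 0; i < n; ++i) p[i] = w[i] * n / total;
    std::vector<int> small, large;
    small.reserve(n); large.reserve(n);
    for (int i = 0; i < n; ++i) (p[i] < 1.0 ? small : large).push_back(i);
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = p[s];
      alias[s] = l;
      p[l] = (p[l] + p[s]) - 1.0;
      (p[l] < 1.0 ? small : large).push_back(l);
    }
    while (!large.empty()) { prob[large.back()] = 1.0; large.pop_back(); }
    while (!small.empty()) { prob[small.back()] = 1.0; small.pop_back(); }
  }

  inline int sample(Xoshiro256& rng) {
    int i = rng.runif_int(n);
    return rng.runif() < prob[i] ? i : alias[i];
  }
};

#endif
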