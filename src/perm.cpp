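#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Self-contained counter-based PRNG (splitmix64) for the permutation
// engines: gives each area its own reproducible substream, so local
// Moran p-values do not depend on the order areas are processed in.
static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double runif01(uint64_t &state) {
  return (splitmix64(state) >> 11) * (1.0 / 9007199254740992.0);
}

// random integer in [0, m)
static inline int runif_int(uint64_t &state, int m) {
  return (int)(runif01(state) * m) % m;
}

// Count permuted global Moran numerators at least as extreme as the
// observed one, in the given direction (+1 upper tail, -1 lower tail).
// The denominator sum(z^2) and the n/S0 factor are permutation
// invariant, so only the cross-product numerator is recomputed.
// [[Rcpp::export]]
int moran_perm_count_cpp(NumericVector z, IntegerVector ei, IntegerVector ej,
                         NumericVector w, double obs_num, int direction,
                         int n_perm, double seed) {
  const int n = z.size(), m = ei.size();
  std::vector<int> perm(n);
  uint64_t state = (uint64_t)seed * 0x9E3779B97F4A7C15ULL + 0x243F6A8885A308D3ULL;
  int count = 0;
  const double eps = 1e-12 * (1.0 + std::fabs(obs_num));
  for (int p = 0; p < n_perm; ++p) {
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = runif_int(state, i + 1);
      std::swap(perm[i], perm[j]);
    }
    double num = 0.0;
    for (int k = 0; k < m; ++k)
      num += w[k] * z[perm[ei[k]]] * z[perm[ej[k]]];
    if (direction >= 0 ? (num >= obs_num - eps) : (num <= obs_num + eps))
      ++count;
  }
  return count;
}

// Conditional permutation test for local Moran's I: for each area i,
// hold z_i fixed and draw its d_i neighbor values from the remaining
// n-1 observations without replacement, n_perm times.  Returns the
// per-area extreme counts; the direction per area is the sign of the
// observed departure from the conditional null expectation.
// [[Rcpp::export]]
IntegerVector lisa_perm_count_cpp(NumericVector z, List neighbors,
                                  List weights, NumericVector obs_lag,
                                  IntegerVector direction, int n_perm,
                                  double seed) {
  const int n = z.size();
  IntegerVector counts(n);
  std::vector<int> pool(n - 1);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = neighbors[i];      // 0-based, unused (sizes only)
    NumericVector wi = weights[i];
    const int d = nb.size();
    if (d == 0) { counts[i] = NA_INTEGER; continue; }
    // per-area substream: independent of processing order
    uint64_t state = ((uint64_t)seed ^ (0x9E3779B97F4A7C15ULL * (uint64_t)(i + 1)))
      + 0x243F6A8885A308D3ULL;
    int k = 0;
    for (int j = 0; j < n; ++j) if (j != i) pool[k++] = j;
    const double eps = 1e-12 * (1.0 + std::fabs(obs_lag[i]));
    int cnt = 0;
    for (int p = 0; p < n_perm; ++p) {
      // partial Fisher-Yates: first d entries are the sampled neighbors
      for (int s = 0; s < d; ++s) {
        int j = s + runif_int(state, n - 1 - s);
        std::swap(pool[s], pool[j]);
      }
      double lag = 0.0;
      for (int s = 0; s < d; ++s) lag += wi[s] * z[pool[s]];
      if (direction[i] >= 0 ? (lag >= obs_lag[i] - eps)
                            : (lag <= obs_lag[i] + eps))
        ++cnt;
    }
    counts[i] = cnt;
  }
  return counts;
}
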