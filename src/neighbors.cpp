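#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

#if defined(__GNUC__) || defined(__clang__)
static inline int popcount64(uint64_t w) { return __builtin_popcountll(w); }
#else
static inline int popcount64(uint64_t w) {
  int c = 0;
  while (w) { w &= w - 1; ++c; }
  return c;
}
#endif

// Per-edge common-neighbor counts via bit-set intersections.
// nPre(i->j)  = |{k : k->i and k->j}|  (common inputs)
// nPost(i->j) = |{k : i->k and j->k}|  (common targets)
// Scales to ~2e7 edges / 2e4 cells in tens of seconds on one core.
// [[Rcpp::export]]
List cpp_common_neighbors(IntegerVector pre, IntegerVector post, int n_cells) {
  const R_xlen_t m = pre.size();
  const int words = (n_cells + 63) / 64;
  std::vector<uint64_t> inb((size_t)n_cells * words, 0);
  std::vector<uint64_t> outb((size_t)n_cells * words, 0);
  for (R_xlen_t e = 0; e < m; ++e) {
    int i = pre[e] - 1, j = post[e] - 1;
    outb[(size_t)i * words + (j >> 6)] |= (uint64_t)1 << (j & 63);
    inb[(size_t)j * words + (i >> 6)] |= (uint64_t)1 << (i & 63);
  }
  IntegerVector npre(m), npost(m);
  for (R_xlen_t e = 0; e < m; ++e) {
    int i = pre[e] - 1, j = post[e] - 1;
    const uint64_t *ii = &inb[(size_t)i * words];
    const uint64_t *ij = &inb[(size_t)j * words];
    const uint64_t *oi = &outb[(size_t)i * words];
    const uint64_t *oj = &outb[(size_t)j * words];
    int a = 0, b = 0;
    for (int w = 0; w < words; ++w) {
      a += popcount64(ii[w] & ij[w]);
      b += popcount64(oi[w] & oj[w]);
    }
    npre[e] = a;
    npost[e] = b;
  }
  return List::create(_["n_pre"] = npre, _["n_post"] = npost);
}

// In-place style amplitude shuffle: n_swaps random transpositions, exactly
// conserving the amplitude multiset. Two RNG draws per swap.
// [[Rcpp::export]]
NumericVector cpp_shuffle_amplitudes(NumericVector amplitude, double n_swaps) {
  NumericVector a = clone(amplitude);
  const double m = (double)a.size();
  if (m < 2) return a;
  for (double s = 0; s < n_swaps; ++s) {
    R_xlen_t i = (R_xlen_t)(unif_rand() * m);
    R_xlen_t j = (R_xlen_t)(unif_rand() * m);
    if (i >= (R_xlen_t)m) i = (R_xlen_t)m - 1;
    if (j >= (R_xlen_t)m) j = (R_xlen_t)m - 1;
    double t = a[i]; a[i] = a[j]; a[j] = t;
  }
  return a;
}
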