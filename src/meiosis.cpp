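#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// One generation of random mating with Poisson recombination.
// H: m x 2N haplotype matrix (0/1), markers in rows so each haplotype is
// a contiguous column; columns 2i, 2i+1 (0-based) form individual i.
// chr_start/chr_end: 0-based marker ranges per chromosome;
// cm_m: per-marker genetic position in Morgans from chromosome start;
// len_m: per-chromosome genetic length in Morgans.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix cpp_next_generation(const IntegerMatrix H, const int n_off,
                                  const IntegerVector chr_start,
                                  const IntegerVector chr_end,
                                  const NumericVector cm_m,
                                  const NumericVector len_m) {
  const int N = H.ncol() / 2;
  const int m = H.nrow();
  const int n_chr = chr_start.size();
  IntegerMatrix out(m, 2 * n_off);

  for (int g = 0; g < 2 * n_off; ++g) {
    const int p = (int)(unif_rand() * N);
    const int *h1 = &H(0, 2 * p);
    const int *h2 = &H(0, 2 * p + 1);
    int *o = &out(0, g);
    for (int c = 0; c < n_chr; ++c) {
      const int a = chr_start[c], b = chr_end[c];
      int src = (unif_rand() < 0.5) ? 0 : 1;
      // crossover positions as a unit-rate Poisson process on the
      // genetic map (sequential exponential gaps; no sort needed)
      double nxt = exp_rand();
      for (int j = a; j <= b; ++j) {
        const double pos = cm_m[j];
        while (nxt <= pos) { src ^= 1; nxt += exp_rand(); }
        o[j] = src ? h2[j] : h1[j];
      }
    }
  }
  return out;
}
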