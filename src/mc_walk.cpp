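#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Literal simulation of the restarting walk over a CSR transition table.
// ptr/nbr/cum describe, per source node, its neighbor ids (0-based) and the
// within-node cumulative move probabilities (last entry 1). seed_idx/seed_cum
// give the restart distribution. Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
IntegerVector mc_walk_counts(IntegerVector ptr, IntegerVector nbr,
                             NumericVector cum, IntegerVector seed_idx,
                             NumericVector seed_cum, double r, int n_steps) {
  const int n = ptr.size() - 1;
  IntegerVector counts(n);
  const int ns = seed_idx.size();

  auto draw_seed = [&]() -> int {
    double u = unif_rand();
    int lo = std::lower_bound(seed_cum.begin(), seed_cum.end(), u) -
             seed_cum.begin();
    if (lo >= ns) lo = ns - 1;
    return seed_idx[lo];
  };

  int cur = draw_seed();
  for (int t = 0; t < n_steps; ++t) {
    counts[cur]++;
    int a = ptr[cur], b = ptr[cur + 1];
    if (unif_rand() < r || a == b) {
      cur = draw_seed();  // restart, also for dangling positions
    } else {
      double u = unif_rand();
      int j = std::lower_bound(cum.begin() + a, cum.begin() + b, u) -
              cum.begin();
      if (j >= b) j = b - 1;
      cur = nbr[j];
    }
  }
  return counts;
}
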