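#include <Rcpp.h>
using namespace Rcpp;

// Draw hard-call genotypes for n individuals at m unlinked variants under
// Hardy-Weinberg equilibrium, via the inverse CDF of Binomial(2, q):
// P(2) = q^2, P(1) = 2q(1-q). Uses R's RNG stream, so results are
// deterministic under set.seed(). Returns the genotype matrix G and the
// heterozygote indicator H (both numeric so downstream BLAS products need
// no coercion).
// [[Rcpp::export(name = ".hwe_draw")]]
List hwe_draw(int n, NumericVector q) {
  int m = q.size();
  NumericMatrix G(n, m), H(n, m);
  for (int j = 0; j < m; ++j) {
    double t2 = q[j] * q[j];          // P(g = 2)
    double t12 = q[j] * (2.0 - q[j]); // P(g >= 1)
    double *g = &G(0, j), *h = &H(0, j);
    for (int i = 0; i < n; ++i) {
      double u = unif_rand();
      if (u < t2) {
        g[i] = 2.0;
      } else if (u < t12) {
        g[i] = 1.0;
        h[i] = 1.0;
      }
    }
  }
  return List::create(_["G"] = G, _["H"] = H);
}
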