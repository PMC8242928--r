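#include <Rcpp.h>
using namespace Rcpp;

// Simulate the 4-state joint-moves chain of a repeated match. `cumtrans` is
// the row-wise cumulative transition matrix; `init` is the 1-based starting
// state. Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
IntegerVector cpp_simulate_chain(NumericMatrix cumtrans, int n_rounds, int init) {
  IntegerVector states(n_rounds);
  int s = init - 1;
  for (int t = 0; t < n_rounds; ++t) {
    double u = unif_rand();
    int ns = 0;
    while (ns < 3 && u > cumtrans(s, ns)) ++ns;
    s = ns;
    states[t] = s + 1;
  }
  return states;
}
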