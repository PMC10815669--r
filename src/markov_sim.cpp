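#include <Rcpp.h>
using namespace Rcpp;

// Simulate a first-order Markov chain over {A,C,G,T} (codes 1..4).
// First base from pi, each following base from the transition row of the
// current base. Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export(name = ".simulate_markov_cpp")]]
IntegerVector simulate_markov_cpp(int n, NumericVector pi,
                                  NumericMatrix trans) {
  if (n < 1) stop("n must be >= 1");
  if (pi.size() != 4 || trans.nrow() != 4 || trans.ncol() != 4)
    stop("pi must have length 4 and trans must be 4x4");

  // cumulative distributions
  double cpi[4];
  double ct[4][4];
  double acc = 0.0;
  for (int j = 0; j < 4; ++j) { acc += pi[j]; cpi[j] = acc; }
  for (int i = 0; i < 4; ++i) {
    acc = 0.0;
    for (int j = 0; j < 4; ++j) { acc += trans(i, j); ct[i][j] = acc; }
  }

  IntegerVector out(n);
  double u = unif_rand() * cpi[3];
  int state = 0;
  while (state < 3 && u > cpi[state]) ++state;
  out[0] = state + 1;
  for (int k = 1; k < n; ++k) {
    u = unif_rand() * ct[state][3];
    int s = 0;
    while (s < 3 && u > ct[state][s]) ++s;
    state = s;
    out[k] = state + 1;
  }
  return out;
}
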