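#include <Rcpp.h>
using namespace Rcpp;

// Sample a DNA string from an order-k Markov chain over {A,C,G,T}.
// `transitions` is a (4^k) x 4 row-stochastic matrix; row index encodes the
// k-mer context in base 4 (A=0, C=1, G=2, T=3), most significant digit first.
// Uses R's RNG so set.seed() on the R side makes the draw reproducible.
// [[Rcpp::export]]
std::string sample_markov_sequence(NumericMatrix transitions, int length,
                                   int order, NumericVector init_probs) {
  if (length < 0) stop("length must be non-negative");
  const int n_ctx = transitions.nrow();
  int expected = 1;
  for (int i = 0; i < order; ++i) expected *= 4;
  if (n_ctx != expected)
    stop("transition matrix must have 4^order rows");
  if (transitions.ncol() != 4)
    stop("transition matrix must have 4 columns");

  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string out(length, 'A');

  // cumulative rows for inverse-CDF sampling
  std::vector<double> cum(n_ctx * 4);
  for (int r = 0; r < n_ctx; ++r) {
    double acc = 0.0;
    for (int c = 0; c < 4; ++c) {
      acc += transitions(r, c);
      cum[r * 4 + c] = acc;
    }
    if (acc <= 0) stop("transition row sums to zero");
    for (int c = 0; c < 4; ++c) cum[r * 4 + c] /= acc;
  }

  double ci[4];
  double acc0 = 0.0;
  for (int c = 0; c < 4; ++c) { acc0 += init_probs[c]; ci[c] = acc0; }
  for (int c = 0; c < 4; ++c) ci[c] /= acc0;

  const int mask = n_ctx - 1;  // n_ctx is a power of 4
  int ctx = 0;
  for (int i = 0; i < length; ++i) {
    double u = unif_rand();
    int b;
    if (i < order) {
      b = 0; while (b < 3 && u > ci[b]) ++b;
    } else {
      const double* row = &cum[ctx * 4];
      b = 0; while (b < 3 && u > row[b]) ++b;
    }
    out[i] = bases[b];
    ctx = ((ctx << 2) | b) & mask;
  }
  return out;
}
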