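#include <Rcpp.h>
using namespace Rcpp;

// Summed-similarity classification probabilities over a growing token store.
//
// One token is stored per past trial; the token's weight is its memory
// strength (delay^-beta, supplied as a lookup table by delay) times its
// similarity to the test stimulus. Similarities are supplied as a T x K
// matrix already exponentiated with the test trial's sensitivity, so the
// kernel is a pure weighted accumulation:
//
//   P(A at trial t) = sum_{j<t, cat_j=A} M[t-j] * sim(t, stim_j) / (sum_A + sum_B)
//
// An empty (or one-sided-empty-total) store yields 0.5.
//
// stim:  1-based stimulus type per trial (length T)
// is_a:  whether each trial's stimulus belongs to category A (token label)
// sim:   ne x K, sim(i, s) = exp(-c_{eval_i} * d(stim_{eval_i}, s))
// mtab:  memory strength by delay, mtab[d-1] = d^-beta (length >= T-1)
// eval:  1-based trial indices at which to return P(A), aligned with sim rows
// [[Rcpp::export]]
NumericVector exemplar_trace_cpp(IntegerVector stim, LogicalVector is_a,
                                 NumericMatrix sim, NumericVector mtab,
                                 IntegerVector eval) {
  const int ne = eval.size();
  NumericVector out(ne);
  for (int i = 0; i < ne; ++i) {
    const int t = eval[i] - 1;
    double sa = 0.0, sb = 0.0;
    for (int j = 0; j < t; ++j) {
      const double w = mtab[t - j - 1] * sim(i, stim[j] - 1);
      if (is_a[j]) sa += w; else sb += w;
    }
    out[i] = (sa + sb > 0.0) ? sa / (sa + sb) : 0.5;
  }
  return out;
}
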