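#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Enrichment score from sorted 1-based hit positions along a ranked list of
// length N with per-position hit weights w (already |stat|^exponent).
// Between hits the running sum falls linearly by 1/(N-k) per miss, so the
// extrema can only occur immediately after a hit (maximum candidates) or
// immediately before a hit (minimum candidates).
static double es_positions(const NumericVector& w, const IntegerVector& pos) {
  const int N = w.size();
  const int k = pos.size();
  double sumw = 0.0;
  for (int i = 0; i < k; ++i) sumw += w[pos[i] - 1];
  const double miss = (N > k) ? 1.0 / (N - k) : 0.0;
  double cum = 0.0, maxdev = 0.0, mindev = 0.0;
  for (int i = 0; i < k; ++i) {
    const double before = cum - (pos[i] - 1 - i) * miss;
    if (before < mindev) mindev = before;
    cum += (sumw > 0.0) ? w[pos[i] - 1] / sumw : 1.0 / k;
    const double after = cum - (pos[i] - i - 1) * miss;
    if (after > maxdev) maxdev = after;
  }
  return (maxdev >= -mindev) ? maxdev : mindev;
}

// [[Rcpp::export]]
double es_from_positions_cpp(NumericVector w, IntegerVector pos) {
  IntegerVector p = clone(pos);
  std::sort(p.begin(), p.end());
  return es_positions(w, p);
}

// Gene-label permutation null: each permutation assigns the set to k
// positions drawn uniformly without replacement (uses the R RNG, so results
// are reproducible under set.seed()).
// [[Rcpp::export]]
NumericVector gsea_perm_es_cpp(NumericVector w, int k, int nperm) {
  const int N = w.size();
  NumericVector out(nperm);
  for (int p = 0; p < nperm; ++p) {
    IntegerVector pos = Rcpp::sample(N, k, false);
    std::sort(pos.begin(), pos.end());
    out[p] = es_positions(w, pos);
  }
  return out;
}
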