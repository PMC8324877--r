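#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exhaustive ordered-triple scan scoring one triad pattern.
//
// W1, W2, W3: weight matrices of the layers assigned to the three link
// positions.  Flux positions: source->middle (W1), middle->sink (W2),
// source->sink (W3).  Cycle positions: i->j (W1), j->k (W2), k->i (W3).
// U: entrywise sum of the pattern's distinct layers; a pattern link
// x->y is admissible only when U(y, x) == 0 (no reciprocal link within
// the layers considered).
//
// Returns c(instance count, sum of instance intensities (w1 w2 w3)^{1/3},
// sum of instance coherences GM/AM).  Cycle rotational symmetry is
// handled by the caller.
// [[Rcpp::export]]
NumericVector triad_scan(NumericMatrix W1, NumericMatrix W2,
                         NumericMatrix W3, NumericMatrix U, bool cycle) {
  const int n = W1.nrow();
  double count = 0.0, isum = 0.0, csum = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      const double w1 = W1(i, j);
      if (w1 <= 0.0 || U(j, i) > 0.0) continue;
      for (int k = 0; k < n; ++k) {
        if (k == i || k == j) continue;
        const double w2 = W2(j, k);
        if (w2 <= 0.0 || U(k, j) > 0.0) continue;
        const double w3 = cycle ? W3(k, i) : W3(i, k);
        if (w3 <= 0.0) continue;
        if (cycle ? (U(i, k) > 0.0) : (U(k, i) > 0.0)) continue;
        const double gm = std::cbrt(w1 * w2 * w3);
        count += 1.0;
        isum += gm;
        csum += 3.0 * gm / (w1 + w2 + w3);
      }
    }
  }
  return NumericVector::create(count, isum, csum);
}
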