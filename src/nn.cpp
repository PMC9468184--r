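// Nearest-neighbour Euclidean distances between two 3D point sets.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
NumericVector nn_dist_cpp(NumericMatrix src, NumericMatrix tgt) {
  const int n = src.nrow(), m = tgt.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double x = src(i, 0), y = src(i, 1), z = src(i, 2);
    for (int j = 0; j < m; ++j) {
      double dx = x - tgt(j, 0), dy = y - tgt(j, 1), dz = z - tgt(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
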