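#include <Rcpp.h>
using namespace Rcpp;

// Online self-organizing map training pass.
//
// data:      n x p observation matrix.
// codebook:  k x p initial codebook (modified copy returned).
// grid:      k x 2 unit coordinates on the rectangular map.
// order:     per-step observation indices (1-based), length = total steps;
//            generated (seeded) on the R side so training is reproducible.
// alpha0/1:  learning rate, decayed linearly over the steps.
// radius0/1: Gaussian neighbourhood radius, decayed linearly.
// [[Rcpp::export]]
NumericMatrix som_train_cpp(const NumericMatrix& data,
                            const NumericMatrix& codebook,
                            const NumericMatrix& grid,
                            const IntegerVector& order,
                            double alpha0, double alpha1,
                            double radius0, double radius1) {
  const int n = data.nrow(), p = data.ncol(), k = codebook.nrow();
  NumericMatrix cb(clone(codebook));
  const R_xlen_t steps = order.size();
  for (R_xlen_t s = 0; s < steps; ++s) {
    const double frac = steps > 1 ? (double)s / (double)(steps - 1) : 0.0;
    const double alpha = alpha0 + (alpha1 - alpha0) * frac;
    const double radius = radius0 + (radius1 - radius0) * frac;
    const int i = order[s] - 1;
    if (i < 0 || i >= n) stop("observation index out of range");
    // best-matching unit
    int bmu = 0;
    double best = R_PosInf;
    for (int u = 0; u < k; ++u) {
      double d = 0.0;
      for (int j = 0; j < p; ++j) {
        const double diff = data(i, j) - cb(u, j);
        d += diff * diff;
      }
      if (d < best) { best = d; bmu = u; }
    }
    // Gaussian neighbourhood update around the BMU's grid position
    const double denom = 2.0 * radius * radius;
    for (int u = 0; u < k; ++u) {
      const double dg0 = grid(u, 0) - grid(bmu, 0);
      const double dg1 = grid(u, 1) - grid(bmu, 1);
      const double h = std::exp(-(dg0 * dg0 + dg1 * dg1) / denom);
      if (h < 1e-12) continue;
      const double step = alpha * h;
      for (int j = 0; j < p; ++j) {
        cb(u, j) += step * (data(i, j) - cb(u, j));
      }
    }
  }
  return cb;
}

// Best-matching unit (1-based) and its squared distance for each row.
// [[Rcpp::export]]
List som_map_cpp(const NumericMatrix& data, const NumericMatrix& codebook) {
  const int n = data.nrow(), p = data.ncol(), k = codebook.nrow();
  IntegerVector bmu(n);
  NumericVector dist2(n);
  for (int i = 0; i < n; ++i) {
    int best_u = 0;
    double best = R_PosInf;
    for (int u = 0; u < k; ++u) {
      double d = 0.0;
      for (int j = 0; j < p; ++j) {
        const double diff = data(i, j) - codebook(u, j);
        d += diff * diff;
      }
      if (d < best) { best = d; best_u = u; }
    }
    bmu[i] = best_u + 1;
    dist2[i] = best;
  }
  return List::create(_["bmu"] = bmu, _["dist2"] = dist2);
}
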