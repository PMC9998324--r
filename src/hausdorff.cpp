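#include <Rcpp.h>
using namespace Rcpp;

// Directed Hausdorff distance between two 3D point sets (rows = points,
// physical coordinates). Exact max-min with the standard early-break:
// scanning of the inner set stops as soon as the running minimum drops
// below the current maximum. Pre-shuffling the inner set (done on the R
// side) makes the break effective.
// [[Rcpp::export]]
double directed_hausdorff_cpp(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  double worst = 0.0;
  for (int i = 0; i < na; ++i) {
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    double cmin = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      const double dx = ax - b(j, 0);
      const double dy = ay - b(j, 1);
      const double dz = az - b(j, 2);
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < cmin) {
        cmin = d;
        if (cmin <= worst) break;
      }
    }
    if (cmin > worst) worst = cmin;
  }
  return std::sqrt(worst);
}
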