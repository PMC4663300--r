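#include <Rcpp.h>
using namespace Rcpp;

// c-means objective J(V) = sum_j (sum_i d_ij^2 ^ (-1/(m-1)))^(1-m)
// (the inner sum collapses: with u_ij from the membership update,
// sum_i u_ij^m d_ij^2 == s_j^(1-m) where s_j = sum_i d_ij^(-2/(m-1))).
// A pixel sitting exactly on a center has membership 1 there and
// contributes 0, matching the zero-distance convention.
// [[Rcpp::export]]
double cpp_fcm_objective(NumericVector centers, NumericVector x, double m) {
  const int c = centers.size();
  const R_xlen_t n = x.size();
  const double expo = -1.0 / (m - 1.0);
  const bool quad = (m == 2.0);
  double J = 0.0;
  for (R_xlen_t j = 0; j < n; ++j) {
    double s = 0.0;
    bool on_center = false;
    for (int i = 0; i < c; ++i) {
      const double d = centers[i] - x[j];
      const double d2 = d * d;
      if (d2 == 0.0) { on_center = true; break; }
      s += quad ? 1.0 / d2 : std::pow(d2, expo);
    }
    if (on_center) continue;
    J += quad ? 1.0 / s : std::pow(s, 1.0 - m);
  }
  return J;
}
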