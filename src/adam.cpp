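// Fused in-place Adam update for one parameter matrix. The caller owns a
// private deep copy of the parameters, so in-place mutation is safe.

#include <Rcpp.h>

// [[Rcpp::export]]
void adam_update_cpp(Rcpp::NumericMatrix W, Rcpp::NumericMatrix G,
                     Rcpp::NumericMatrix M, Rcpp::NumericMatrix V, double lr,
                     double beta1, double beta2, double bc1, double bc2,
                     double eps) {
  R_xlen_t n = W.size();
  double* w = W.begin();
  double* g = G.begin();
  double* m = M.begin();
  double* v = V.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    m[i] = beta1 * m[i] + (1.0 - beta1) * g[i];
    v[i] = beta2 * v[i] + (1.0 - beta2) * g[i] * g[i];
    w[i] -= lr * (m[i] / bc1) / (std::sqrt(v[i] / bc2) + eps);
  }
}
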