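#include <Rcpp.h>
using namespace Rcpp;

// In-place Adam update for one parameter tensor. The parameter and its
// first/second moment buffers are owned exclusively by the training loop,
// so updating them in place avoids copying the multi-megabyte dense layers
// of the denoiser on every optimization step.
// [[Rcpp::export]]
void adam_update_inplace(NumericVector p, NumericVector g,
                         NumericVector m, NumericVector v,
                         int t, double lr, double beta1, double beta2,
                         double eps) {
  const R_xlen_t n = p.size();
  if (g.size() != n || m.size() != n || v.size() != n) {
    stop("parameter/gradient/moment sizes differ");
  }
  const double c1 = 1.0 - std::pow(beta1, t);
  const double c2 = 1.0 - std::pow(beta2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = g[i];
    m[i] = beta1 * m[i] + (1.0 - beta1) * gi;
    v[i] = beta2 * v[i] + (1.0 - beta2) * gi * gi;
    p[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
}

// Multiply a numeric tensor by a scalar in place (gradient clipping).
// [[Rcpp::export]]
void scale_inplace(NumericVector x, double s) {
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) x[i] *= s;
}
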