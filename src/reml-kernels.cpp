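// Dense kernels for the AI-REML engine: allocation-free trace products
// and in-place assembly of V = sum_k theta_k V_k, which dominate the
// per-iteration cost at field-trial problem sizes (n in the thousands).

#include <Rcpp.h>
using namespace Rcpp;

// sum(A * B) without materialising the elementwise product
// [[Rcpp::export(name = ".trace_hadamard")]]
double trace_hadamard(const NumericMatrix& A, const NumericMatrix& B) {
  const R_xlen_t n = A.size();
  if (B.size() != n) stop("dimension mismatch");
  long double s = 0.0;
  const double* a = A.begin();
  const double* b = B.begin();
  for (R_xlen_t i = 0; i < n; ++i) s += a[i] * b[i];
  return (double)s;
}

// V = sum_k theta[k] * mats[[k]] + diag_add * I, assembled in one pass
// [[Rcpp::export(name = ".weighted_mat_sum")]]
NumericMatrix weighted_mat_sum(const List& mats, const NumericVector& theta,
                               const double diag_add, const int n) {
  NumericMatrix V(n, n);
  double* v = V.begin();
  const R_xlen_t nn = (R_xlen_t)n * n;
  for (int k = 0; k < mats.size(); ++k) {
    if (Rf_isNull(mats[k])) continue;
    NumericMatrix M = mats[k];
    if (M.size() != nn) stop("dimension mismatch in component %d", k + 1);
    const double t = theta[k];
    if (t == 0.0) continue;
    const double* m = M.begin();
    for (R_xlen_t i = 0; i < nn; ++i) v[i] += t * m[i];
  }
  if (diag_add != 0.0) {
    for (int j = 0; j < n; ++j) v[(R_xlen_t)j * n + j] += diag_add;
  }
  return V;
}
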