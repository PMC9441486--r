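#include <Rcpp.h>
using namespace Rcpp;

// Gather im2col patches: X is (HW x C) channel-columns, idx is
// (HWo x K) 1-based linear pixel indices. Output is (HWo x K*C) with
// column layout j = (k-1)*C + c, matching the weight-row layout.
// [[Rcpp::export]]
NumericMatrix cpp_gather(const NumericMatrix& X, const IntegerMatrix& idx) {
  const int HWo = idx.nrow(), K = idx.ncol(), C = X.ncol();
  const int HW = X.nrow();
  NumericMatrix out(HWo, K * C);
  const double* px = X.begin();
  const int* pi = idx.begin();
  double* po = out.begin();
  for (int k = 0; k < K; ++k) {
    const int* ik = pi + (size_t)k * HWo;
    for (int c = 0; c < C; ++c) {
      const double* xc = px + (size_t)c * HW;
      double* oc = po + ((size_t)k * C + c) * HWo;
      for (int i = 0; i < HWo; ++i) oc[i] = xc[ik[i] - 1];
    }
  }
  return out;
}

// Scatter-add the patch gradient back to pixel space: dP is
// (HWo x K*C), idx as above; returns (HW x C).
// [[Rcpp::export]]
NumericMatrix cpp_scatter_add(const NumericMatrix& dP,
                              const IntegerMatrix& idx, const int HW) {
  const int HWo = idx.nrow(), K = idx.ncol();
  const int C = dP.ncol() / K;
  NumericMatrix out(HW, C);
  const double* pd = dP.begin();
  const int* pi = idx.begin();
  double* po = out.begin();
  for (int k = 0; k < K; ++k) {
    const int* ik = pi + (size_t)k * HWo;
    for (int c = 0; c < C; ++c) {
      const double* dc = pd + ((size_t)k * C + c) * HWo;
      double* oc = po + (size_t)c * HW;
      for (int i = 0; i < HWo; ++i) oc[ik[i] - 1] += dc[i];
    }
  }
  return out;
}

// Per-column affine map Y = X * a[c] + b[c] in one pass (used by the
// batch-norm layers to avoid materializing broadcast matrices).
// [[Rcpp::export]]
NumericMatrix cpp_col_affine(const NumericMatrix& X, const NumericVector& a,
                             const NumericVector& b) {
  const int n = X.nrow(), C = X.ncol();
  NumericMatrix out(n, C);
  const double* px = X.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c) {
    const double ac = a[c], bc = b[c];
    const double* xc = px + (size_t)c * n;
    double* oc = po + (size_t)c * n;
    for (int i = 0; i < n; ++i) oc[i] = xc[i] * ac + bc;
  }
  return out;
}

// Column sums of an elementwise product, without the temporary.
// [[Rcpp::export]]
NumericVector cpp_colsums_prod(const NumericMatrix& A,
                               const NumericMatrix& B) {
  const int n = A.nrow(), C = A.ncol();
  NumericVector out(C);
  const double* pa = A.begin();
  const double* pb = B.begin();
  for (int c = 0; c < C; ++c) {
    const double* ac = pa + (size_t)c * n;
    const double* bc = pb + (size_t)c * n;
    double s = 0;
    for (int i = 0; i < n; ++i) s += ac[i] * bc[i];
    out[c] = s;
  }
  return out;
}

// Batch-norm input gradient:
// dX[,c] = (dY[,c]*gamma[c] - dbeta[c]/n - xhat[,c]*dgamma[c]/n) * inv[c]
// [[Rcpp::export]]
NumericMatrix cpp_bn_bwd_dx(const NumericMatrix& dY,
                            const NumericMatrix& xhat,
                            const NumericVector& gamma,
                            const NumericVector& inv,
                            const NumericVector& dgamma,
                            const NumericVector& dbeta) {
  const int n = dY.nrow(), C = dY.ncol();
  NumericMatrix out(n, C);
  const double* pd = dY.begin();
  const double* ph = xhat.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c) {
    const double g = gamma[c], iv = inv[c];
    const double b1 = dbeta[c] * g / n, g1 = dgamma[c] * g / n;
    const double* dc = pd + (size_t)c * n;
    const double* hc = ph + (size_t)c * n;
    double* oc = po + (size_t)c * n;
    for (int i = 0; i < n; ++i) {
      oc[i] = (dc[i] * g - b1 - hc[i] * g1) * iv;
    }
  }
  return out;
}
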