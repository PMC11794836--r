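#include <Rcpp.h>
using namespace Rcpp;

// Row gather for im2col: out[i, j] = X[idx[i], j], with idx == 0 meaning a
// zero-padded source (outside the image). idx is 1-based.
// [[Rcpp::export]]
NumericMatrix kd_gather(const NumericMatrix& X, const IntegerVector& idx) {
  const int m = idx.size(), n = X.ncol();
  NumericMatrix out(m, n);
  for (int j = 0; j < n; ++j) {
    const double* xj = &X(0, j);
    double* oj = &out(0, j);
    for (int i = 0; i < m; ++i) {
      const int s = idx[i];
      oj[i] = (s > 0) ? xj[s - 1] : 0.0;
    }
  }
  return out;
}

// Adjoint of kd_gather: out[idx[i], j] += dP[i, j], idx == 0 dropped.
// [[Rcpp::export]]
NumericMatrix kd_scatter(const NumericMatrix& dP, const IntegerVector& idx,
                         const int nrow_out) {
  const int m = idx.size(), n = dP.ncol();
  NumericMatrix out(nrow_out, n);
  for (int j = 0; j < n; ++j) {
    const double* dj = &dP(0, j);
    double* oj = &out(0, j);
    for (int i = 0; i < m; ++i) {
      const int s = idx[i];
      if (s > 0) oj[s - 1] += dj[i];
    }
  }
  return out;
}
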