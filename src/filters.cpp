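#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Direct-form II transposed IIR filter, a[0] must be 1 (normalized by caller).
static void iir_pass(const std::vector<double>& b, const std::vector<double>& a,
                     double* x, int n) {
  int nb = b.size(), na = a.size();
  int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + (nz > 0 ? z[0] : 0.0);
    for (int j = 0; j < nz - 1; ++j) {
      double bj = (j + 1 < nb) ? b[j + 1] : 0.0;
      double aj = (j + 1 < na) ? a[j + 1] : 0.0;
      z[j] = bj * xi + z[j + 1] - aj * yi;
    }
    if (nz > 0) {
      double bl = (nz < nb) ? b[nz] : 0.0;
      double al = (nz < na) ? a[nz] : 0.0;
      z[nz - 1] = bl * xi - al * yi;
    }
    x[i] = yi;
  }
}

// [[Rcpp::export]]
NumericVector cpp_iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  double a0 = aa[0];
  for (auto& v : bb) v /= a0;
  for (auto& v : aa) v /= a0;
  NumericVector y = clone(x);
  iir_pass(bb, aa, REAL(y), y.size());
  return y;
}

// Zero-phase (forward-backward) filtering of one signal with odd-reflection
// padding of `pad` samples at each end.
static void filtfilt_one(const std::vector<double>& b, const std::vector<double>& a,
                         const double* x, double* y, int n, int pad) {
  std::vector<double> ext(n + 2 * pad);
  for (int i = 0; i < pad; ++i) ext[i] = 2.0 * x[0] - x[pad - i];
  std::copy(x, x + n, ext.begin() + pad);
  for (int i = 0; i < pad; ++i) ext[pad + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];
  int m = ext.size();
  iir_pass(b, a, ext.data(), m);
  std::reverse(ext.begin(), ext.end());
  iir_pass(b, a, ext.data(), m);
  std::reverse(ext.begin(), ext.end());
  std::copy(ext.begin() + pad, ext.begin() + pad + n, y);
}

// [[Rcpp::export]]
NumericVector cpp_filtfilt(NumericVector b, NumericVector a, NumericVector x, int pad) {
  int n = x.size();
  if (pad > n - 1) pad = n - 1;
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  double a0 = aa[0];
  for (auto& v : bb) v /= a0;
  for (auto& v : aa) v /= a0;
  NumericVector y(n);
  filtfilt_one(bb, aa, REAL(x), REAL(y), n, pad);
  return y;
}

// Zero-phase filtering applied to every row of a channels x samples matrix.
// [[Rcpp::export]]
NumericMatrix cpp_filtfilt_rows(NumericVector b, NumericVector a, NumericMatrix X, int pad) {
  int nc = X.nrow(), n = X.ncol();
  if (pad > n - 1) pad = n - 1;
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  double a0 = aa[0];
  for (auto& v : bb) v /= a0;
  for (auto& v : aa) v /= a0;
  NumericMatrix Y(nc, n);
  std::vector<double> row(n), out(n);
  for (int c = 0; c < nc; ++c) {
    for (int i = 0; i < n; ++i) row[i] = X(c, i);
    filtfilt_one(bb, aa, row.data(), out.data(), n, pad);
    for (int i = 0; i < n; ++i) Y(c, i) = out[i];
  }
  return Y;
}

// Median over selected rows, per column (per-sample median across channels).
// [[Rcpp::export]]
NumericVector cpp_col_medians(NumericMatrix X, IntegerVector rows) {
  int n = X.ncol(), k = rows.size();
  NumericVector out(n);
  std::vector<double> buf(k);
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < k; ++i) buf[i] = X(rows[i] - 1, j);
    int h = k / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double med = buf[h];
    if (k % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + h);
      med = 0.5 * (med + lo);
    }
    out[j] = med;
  }
  return out;
}
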