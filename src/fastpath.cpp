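#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// from rng.cpp
NumericVector cpp_randn(int n, double seed);

// Common-median re-reference, in place, on rows first..first+m-1 (1-based
// `first`) of a samples x channels matrix: subtract the per-sample median
// across `cols` (1-based) from all columns, returning the median signal.
// Processed in row chunks via a transposed buffer to stay cache-resident.
// [[Rcpp::export]]
NumericVector cpp_cmr_range(NumericMatrix X, int first, int m, IntegerVector cols) {
  int n = X.nrow(), nc = X.ncol(), k = cols.size();
  int base = first - 1;
  const int CH = 4096;
  std::vector<double> buf(static_cast<size_t>(CH) * k), row(k);
  NumericVector med(m);
  double* x = REAL(X);
  int h = k / 2;
  for (int i0 = 0; i0 < m; i0 += CH) {
    int mm = std::min(CH, m - i0);
    for (int j = 0; j < k; ++j) {
      double* colp = x + static_cast<size_t>(cols[j] - 1) * n + base + i0;
      std::copy(colp, colp + mm, buf.data() + static_cast<size_t>(j) * CH);
    }
    for (int r = 0; r < mm; ++r) {
      for (int j = 0; j < k; ++j) row[j] = buf[static_cast<size_t>(j) * CH + r];
      std::nth_element(row.begin(), row.begin() + h, row.end());
      double md = row[h];
      if (k % 2 == 0) md = 0.5 * (md + *std::max_element(row.begin(), row.begin() + h));
      med[i0 + r] = md;
    }
    for (int j = 0; j < nc; ++j) {
      double* colp = x + static_cast<size_t>(j) * n + base + i0;
      for (int r = 0; r < mm; ++r) colp[r] -= med[i0 + r];
    }
  }
  return med;
}

// Unpack a packed two-channel forward FFT W = fft(x1 + i x2) into band
// slices multiplied by the band response, folded modulo Lr (exact
// time-domain subsampling). `sups` holds 0-based positive-frequency bins.
// Returns, per band, an Lr x (1 or 2) complex matrix ready for inverse FFT.
// [[Rcpp::export]]
List cpp_unpack_slices(ComplexVector W, List sups, List h2s,
                       IntegerVector Lrs, bool two) {
  int L = W.size();
  int nb = sups.size();
  List out(nb);
  for (int b = 0; b < nb; ++b) {
    IntegerVector sup = sups[b];
    NumericVector h2 = h2s[b];
    int Lr = Lrs[b];
    ComplexMatrix Sb(Lr, two ? 2 : 1);
    for (int i = 0; i < sup.size(); ++i) {
      int j = sup[i];
      Rcomplex wj = W[j], wm = W[L - j];
      int pos = j % Lr;  // demodulation-free folding keeps absolute bins
      double h = h2[i];
      if (two) {
        double x1r = 0.5 * (wj.r + wm.r), x1i = 0.5 * (wj.i - wm.i);
        double nr = wj.r - wm.r, ni = wj.i + wm.i;
        double x2r = 0.5 * ni, x2i = -0.5 * nr;
        Sb(pos, 0).r += h * x1r;  Sb(pos, 0).i += h * x1i;
        Sb(pos, 1).r += h * x2r;  Sb(pos, 1).i += h * x2i;
      } else {
        Sb(pos, 0).r += h * wj.r;  Sb(pos, 0).i += h * wj.i;
      }
    }
    out[b] = Sb;
  }
  return out;
}

// Envelope bin means: |Z| scaled, averaged over bpb consecutive bins.
// [[Rcpp::export]]
NumericMatrix cpp_env_bin_means(ComplexMatrix Z, int bpb, double scale) {
  int Lr = Z.nrow(), nc = Z.ncol(), K = Lr / bpb;
  NumericMatrix out(bpb, nc);
  for (int c = 0; c < nc; ++c) {
    for (int bin = 0; bin < bpb; ++bin) {
      double s = 0;
      for (int r = bin * K; r < (bin + 1) * K; ++r) {
        s += std::sqrt(Z(r, c).r * Z(r, c).r + Z(r, c).i * Z(r, c).i);
      }
      out(bin, c) = s * scale / K;
    }
  }
  return out;
}

// Per-column standard deviation (two-pass) of a samples x channels matrix.
// [[Rcpp::export]]
NumericVector cpp_col_sd(NumericMatrix X) {
  int n = X.nrow(), nc = X.ncol();
  NumericVector out(nc);
  for (int j = 0; j < nc; ++j) {
    double m = 0;
    for (int i = 0; i < n; ++i) m += X(i, j);
    m /= n;
    double s = 0;
    for (int i = 0; i < n; ++i) { double d = X(i, j) - m; s += d * d; }
    out[j] = std::sqrt(s / (n - 1));
  }
  return out;
}

// Count samples with |x| > thr per (segment, selected channel);
// segments are consecutive windows of `w` samples. `cols` is 1-based.
// [[Rcpp::export]]
IntegerMatrix cpp_supra_counts(NumericMatrix X, int w, NumericVector thr,
                               IntegerVector cols) {
  int nseg = X.nrow() / w;
  int k = cols.size();
  IntegerMatrix out(nseg, k);
  for (int j = 0; j < k; ++j) {
    int col = cols[j] - 1;
    double t = thr[j];
    for (int s = 0; s < nseg; ++s) {
      int cnt = 0;
      int i0 = s * w, i1 = (s + 1) * w;
      for (int i = i0; i < i1; ++i) {
        if (std::fabs(X(i, col)) > t) ++cnt;
      }
      out(s, j) = cnt;
    }
  }
  return out;
}

// Assemble the filtered block spectra for all channels of one block,
// packed in channel pairs: output column p holds S_{2p} + i * S_{2p+1}
// (0-based), where S_c = (pink_c + carriers_c) * H2. `carriers` is an
// nbands x nch complex matrix of the +frequency carrier coefficients and
// `kb` the 0-based carrier bins; `seeds` keys the per-channel pink streams.
// [[Rcpp::export]]
ComplexMatrix cpp_block_spectra_packed(int L, NumericVector w, double scale,
                                       NumericVector seeds, NumericVector H2full,
                                       IntegerVector kb, ComplexMatrix carriers) {
  int nch = seeds.size();
  int half = L / 2;
  int npair = (nch + 1) / 2;
  int nb = kb.size();
  bool pink = w.size() > 0;
  ComplexMatrix out(L, npair);
  std::vector<double> re(L), im(L);
  for (int c = 0; c < nch; ++c) {
    std::fill(re.begin(), re.end(), 0.0);
    std::fill(im.begin(), im.end(), 0.0);
    if (pink) {
      NumericVector g = cpp_randn(2 * (half - 1) + 1, seeds[c]);
      for (int k = 1; k < half; ++k) {
        double wr = w[k - 1] * scale;
        double a = g[2 * (k - 1)] * wr, b = g[2 * (k - 1) + 1] * wr;
        re[k] = a;  im[k] = b;
        re[L - k] = a;  im[L - k] = -b;
      }
      re[half] = g[2 * (half - 1)] * w[half - 1] * scale;
    }
    for (int b = 0; b < nb; ++b) {
      int k = kb[b];
      re[k] += carriers(b, c).r;  im[k] += carriers(b, c).i;
      re[L - k] += carriers(b, c).r;  im[L - k] -= carriers(b, c).i;
    }
    int p = c / 2;
    if (c % 2 == 0) {
      for (int k = 0; k < L; ++k) {
        out(k, p).r = re[k] * H2full[k];
        out(k, p).i = im[k] * H2full[k];
      }
    } else {
      // add i * S_c
      for (int k = 0; k < L; ++k) {
        out(k, p).r -= im[k] * H2full[k];
        out(k, p).i += re[k] * H2full[k];
      }
    }
  }
  return out;
}
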