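#include <Rcpp.h>
using namespace Rcpp;

// 2-D convolution with replicate padding, "same"-size output.
// True convolution (kernel flipped), so an impulse reproduces the kernel
// un-mirrored around the impulse. Zero taps are skipped. The interior is
// accumulated tap-by-tap with contiguous shifted adds; border pixels are
// recomputed with index clamping (replicate padding).
// [[Rcpp::export]]
NumericMatrix conv2_replicate_cpp(const NumericMatrix& x, const NumericMatrix& w) {
  const int nr = x.nrow(), nc = x.ncol();
  const int kr = w.nrow(), kc = w.ncol();
  const int rr = kr / 2, rc = kc / 2;

  std::vector<int> ka, kb;
  std::vector<double> kv;
  for (int b = 0; b < kc; ++b) {
    for (int a = 0; a < kr; ++a) {
      const double v = w(a, b);
      if (v != 0.0) { ka.push_back(a - rr); kb.push_back(b - rc); kv.push_back(v); }
    }
  }
  const int nk = static_cast<int>(kv.size());
  const double* xp = x.begin();

  NumericMatrix out(nr, nc);
  double* op = out.begin();

  // interior: rows rr..nr-rr-1, cols rc..nc-rc-1 (no clamping needed)
  const int i0 = rr, i1 = nr - rr;   // [i0, i1)
  const int j0 = rc, j1 = nc - rc;   // [j0, j1)
  if (i1 > i0 && j1 > j0) {
    for (int q = 0; q < nk; ++q) {
      const double v = kv[q];
      const int di = ka[q], dj = kb[q];
      for (int j = j0; j < j1; ++j) {
        const double* src = xp + (size_t)(j - dj) * nr + (i0 - di);
        double* dst = op + (size_t)j * nr + i0;
        const int n = i1 - i0;
        for (int i = 0; i < n; ++i) dst[i] += v * src[i];
      }
    }
  }

  // borders: full clamped computation
  const bool has_interior = (i1 > i0 && j1 > j0);
  for (int j = 0; j < nc; ++j) {
    const bool jin = (j >= j0 && j < j1);
    for (int i = 0; i < nr; ++i) {
      if (has_interior && jin && i >= i0 && i < i1) { i = i1 - 1; continue; }
      double acc = 0.0;
      for (int q = 0; q < nk; ++q) {
        int ii = i - ka[q];
        int jj = j - kb[q];
        if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
        if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
        acc += kv[q] * xp[(size_t)jj * nr + ii];
      }
      op[(size_t)j * nr + i] = acc;
    }
  }
  return out;
}
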