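#include <Rcpp.h>
using namespace Rcpp;

// Boundary codes: 0 = zero pad, 1 = symmetric (half-sample mirror),
// 2 = periodic, 3 = replicate edge.
static inline int fold(int i, int n, int mode) {
  if (i >= 0 && i < n) return i;
  switch (mode) {
  case 2: { i %= n; if (i < 0) i += n; return i; }
  case 3: return i < 0 ? 0 : n - 1;
  case 1: {
    int m = 2 * n;
    i %= m; if (i < 0) i += m;
    return i < n ? i : m - 1 - i;
  }
  default: return -1;  // zero padding: caller skips
  }
}

// Padded 2-D correlation: out(i,j) = sum_{a,b} k(a,b) x(i+a-cr, j+b-cc)
// with the kernel center at (floor(kr/2), floor(kc/2)). All NSCT / feature /
// template kernels in this package are point-symmetric, so correlation and
// convolution coincide for them; Sobel kernels are used consistently as
// correlations.
// [[Rcpp::export(name = ".conv2Pad")]]
NumericMatrix conv2_pad(const NumericMatrix& x, const NumericMatrix& k, int mode) {
  const int m = x.nrow(), n = x.ncol();
  const int kr = k.nrow(), kc = k.ncol();
  const int cr = kr / 2, cc = kc / 2;
  NumericMatrix out(m, n);
  for (int b = 0; b < kc; ++b) {
    for (int a = 0; a < kr; ++a) {
      const double w = k(a, b);
      if (w == 0.0) continue;
      const int dr = a - cr, dc = b - cc;
      for (int j = 0; j < n; ++j) {
        const int jj = fold(j + dc, n, mode);
        if (jj < 0) continue;
        for (int i = 0; i < m; ++i) {
          const int ii = fold(i + dr, m, mode);
          if (ii < 0) continue;
          out(i, j) += w * x(ii, jj);
        }
      }
    }
  }
  return out;
}
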