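#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Simplified PCNN recursion, iterated nIter times from L = 0, Y = 0,
// theta = thetaInit:
//   F[n]     = S                                  (no feeding memory)
//   L[n]     = exp(-alphaL) L[n-1] + VL * (W (*) Y[n-1])
//   U[n]     = F[n] (1 + beta L[n])
//   theta[n] = exp(-alphaTheta) theta[n-1] + Vtheta * Y[n]
//   Y[n]     = 1  iff  U[n] >= exp(-alphaTheta) theta[n-1]
// i.e. the threshold decays, firing is decided against the decayed value,
// and the Vtheta kick from Y[n] is applied afterwards. Returns the per-pixel
// cumulative firing count. linkMode: 0 = zero padding (border neurons have
// fewer neighbours), 2 = periodic (torus linking, for shift-invariance).
// [[Rcpp::export(name = ".pcnnRun")]]
IntegerMatrix pcnn_run(const NumericMatrix& S, const NumericMatrix& beta,
                       const NumericMatrix& W, double alphaL, double alphaTheta,
                       double VL, double Vtheta, double thetaInit, int nIter,
                       int linkMode) {
  const int m = S.nrow(), n = S.ncol();
  const int wr = W.nrow(), wc = W.ncol();
  const int cr = wr / 2, cc = wc / 2;
  const double dL = std::exp(-alphaL), dT = std::exp(-alphaTheta);

  NumericMatrix L(m, n), theta(m, n);
  IntegerMatrix Y(m, n), counts(m, n);
  std::fill(theta.begin(), theta.end(), thetaInit);

  for (int it = 0; it < nIter; ++it) {
    // gather linking input from the previous iteration's pulses
    NumericMatrix link(m, n);
    for (int j = 0; j < n; ++j) {
      for (int i = 0; i < m; ++i) {
        double acc = 0.0;
        for (int b = 0; b < wc; ++b) {
          for (int a = 0; a < wr; ++a) {
            const double w = W(a, b);
            if (w == 0.0) continue;
            int ii = i + a - cr, jj = j + b - cc;
            if (linkMode == 2) {
              ii %= m; if (ii < 0) ii += m;
              jj %= n; if (jj < 0) jj += n;
            } else if (ii < 0 || ii >= m || jj < 0 || jj >= n) {
              continue;
            }
            if (Y(ii, jj)) acc += w;
          }
        }
        link(i, j) = acc;
      }
    }
    for (int j = 0; j < n; ++j) {
      for (int i = 0; i < m; ++i) {
        const double Lnew = dL * L(i, j) + VL * link(i, j);
        const double U = S(i, j) * (1.0 + beta(i, j) * Lnew);
        const double thDecayed = dT * theta(i, j);
        const int y = (U >= thDecayed) ? 1 : 0;
        L(i, j) = Lnew;
        theta(i, j) = thDecayed + Vtheta * y;
        Y(i, j) = y;
        if (y) ++counts(i, j);
      }
    }
  }
  return counts;
}
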