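// Memory-kernel extraction from a normalized ACF: the once-differentiated
// (second-kind) Volterra memory equation
//
//   -g''(t) - a g'(t) = K(t) g(0) + h * sum_j w_j K(t_j) g'(t - t_j)
//
// with the singular kernel component split off analytically as the delta
// mass a = -g'(0)/g(0). Derivatives by finite differences (order 2 or 4),
// convolution by Gregory-corrected trapezoid quadrature. The order-2 scheme
// is exactly invertible by stable forward marching (reconstruct); the
// order-4 scheme is more accurate on smooth kernels but its inverse
// marching carries a parasitic root ~13.9 and is only usable on short
// prefixes.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gregory weight w_j for the composite quadrature over [0, n h]
static inline double wt(int j, int n, int order) {
  if (order <= 1 || n == 1) return (j == 0 || j == n) ? 0.5 : 1.0;
  if (n == 2) return (j == 1) ? 7.0 / 6.0 : 5.0 / 12.0;
  const int d = (j < n - j) ? j : n - j;  // distance to nearer end
  if (order >= 3 && n >= 5) {
    if (d == 0) return 3.0 / 8.0;
    if (d == 1) return 7.0 / 6.0;
    if (d == 2) return 23.0 / 24.0;
    return 1.0;
  }
  if (d == 0) return 5.0 / 12.0;
  if (d == 1) return 13.0 / 12.0;
  return 1.0;
}

// sum_{j=0}^{n-1} w_j K_j d1[n-j]: weight-1 base sum + O(1) end corrections
static inline double conv_sum(const double* K, const double* d1, int n,
                              int order) {
  if (n < 8) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += wt(j, n, order) * K[j] * d1[n - j];
    return s;
  }
  double s = 0.0;
  for (int j = 0; j < n; ++j) s += K[j] * d1[n - j];
  for (int j = 0; j <= 2; ++j)
    s += (wt(j, n, order) - 1.0) * K[j] * d1[n - j];
  for (int j = n - 2; j <= n - 1; ++j)
    s += (wt(j, n, order) - 1.0) * K[j] * d1[n - j];
  return s;
}

// first/second derivative arrays at t_0..t_{mmax}; N = last index of g
static void deriv_arrays(const std::vector<double>& g, double h, int ord,
                         int mmax, std::vector<double>& d1,
                         std::vector<double>& d2) {
  d1.assign(mmax + 1, 0.0);
  d2.assign(mmax + 1, 0.0);
  const double h2 = h * h;
  if (ord == 2) {
    d1[0] = (-3.0 * g[0] + 4.0 * g[1] - g[2]) / (2.0 * h);
    d2[0] = (2.0 * g[0] - 5.0 * g[1] + 4.0 * g[2] - g[3]) / h2;
    for (int m = 1; m <= mmax; ++m) {
      d1[m] = (g[m + 1] - g[m - 1]) / (2.0 * h);
      d2[m] = (g[m + 1] - 2.0 * g[m] + g[m - 1]) / h2;
    }
  } else {
    d1[0] = (-25.0 * g[0] + 48.0 * g[1] - 36.0 * g[2] + 16.0 * g[3] -
             3.0 * g[4]) / (12.0 * h);
    d2[0] = (45.0 * g[0] - 154.0 * g[1] + 214.0 * g[2] - 156.0 * g[3] +
             61.0 * g[4] - 10.0 * g[5]) / (12.0 * h2);
    if (mmax >= 1) {
      d1[1] = (-3.0 * g[0] - 10.0 * g[1] + 18.0 * g[2] - 6.0 * g[3] +
               g[4]) / (12.0 * h);
      d2[1] = (10.0 * g[0] - 15.0 * g[1] - 4.0 * g[2] + 14.0 * g[3] -
               6.0 * g[4] + g[5]) / (12.0 * h2);
    }
    for (int m = 2; m <= mmax; ++m) {
      d1[m] = (g[m - 2] - 8.0 * g[m - 1] + 8.0 * g[m + 1] - g[m + 2]) /
              (12.0 * h);
      d2[m] = (-g[m - 2] + 16.0 * g[m - 1] - 30.0 * g[m] +
               16.0 * g[m + 1] - g[m + 2]) / (12.0 * h2);
    }
  }
}

// [[Rcpp::export]]
List volterra_solve_cpp(NumericVector g_, double h, int greg, int ord,
                        double pivot_tol) {
  const int N = g_.size() - 1;
  std::vector<double> g(g_.begin(), g_.end());
  const int M = (ord == 2) ? (N - 1) : (N - 2);  // K_0..K_M
  std::vector<double> d1, d2;
  deriv_arrays(g, h, ord, M, d1, d2);
  const double g0 = g[0];
  const double a = -d1[0] / g0;
  std::vector<double> K(M + 1);
  K[0] = (-d2[0] - a * d1[0]) / g0;
  for (int n = 1; n <= M; ++n) {
    const double s = conv_sum(K.data(), d1.data(), n, greg);
    const double piv = g0 + h * wt(n, n, greg) * d1[0];
    if (std::fabs(piv) < pivot_tol)
      stop("singular pivot %g at lag index %d", piv, n);
    K[n] = (-d2[n] - a * d1[n] - h * s) / piv;
  }
  return List::create(_["a"] = a, _["K"] = NumericVector(K.begin(), K.end()));
}

// order-2 inverse marching: exact algebraic inverse of the order-2 solve
// [[Rcpp::export]]
NumericVector volterra_reconstruct2_cpp(double a, NumericVector K_, double h,
                                        int greg, double g0) {
  const int M = K_.size() - 1;  // K_0..K_M; reconstruct g_0..g_{M+1}
  const int N = M + 1;
  std::vector<double> K(K_.begin(), K_.end());
  std::vector<double> g(N + 1, 0.0), d1(N, 0.0);
  g[0] = g0;
  d1[0] = -a * g0;  // identical to the one-sided stencil by the a-definition
  const double h2 = h * h;
  // 2x2 block {a-def, eq1} for (g1, g2)
  {
    const double w0 = wt(0, 1, greg), w1 = wt(1, 1, greg);
    // a-def: (-3 g0 + 4 g1 - g2)/(2h) + a g0 = 0
    const double A11 = 4.0 / (2.0 * h), A12 = -1.0 / (2.0 * h);
    const double b1 = -(-3.0 * g0 / (2.0 * h) + a * g0);
    // eq1: -(g2 - 2 g1 + g0)/h^2 - a (g2 - g0)/(2h) - K1 g0
    //      - h [ w0 K0 (g2 - g0)/(2h) + w1 K1 d1[0] ] = 0
    const double A21 = 2.0 / h2;
    const double A22 = -1.0 / h2 - a / (2.0 * h) - w0 * K[0] / 2.0;
    const double b2 = -(-g0 / h2 + a * g0 / (2.0 * h) - K[1] * g0 +
                        w0 * K[0] * g0 / 2.0 + h * w1 * K[1] * a * g0);
    const double det = A11 * A22 - A12 * A21;
    g[1] = (b1 * A22 - A12 * b2) / det;
    g[2] = (A11 * b2 - b1 * A21) / det;
  }
  d1[1] = (g[2] - g0) / (2.0 * h);
  for (int n = 2; n <= N - 1; ++n) {
    // j = n term (d1[0]) + history j = 1..n-1; j = 0 handled via unknown
    double s = wt(n, n, greg) * K[n] * d1[0];
    if (n < 10) {
      for (int j = 1; j < n; ++j) s += wt(j, n, greg) * K[j] * d1[n - j];
    } else {
      for (int j = 1; j < n; ++j) s += K[j] * d1[n - j];
      for (int j = 1; j <= 2; ++j)
        s += (wt(j, n, greg) - 1.0) * K[j] * d1[n - j];
      for (int j = n - 2; j <= n - 1; ++j)
        s += (wt(j, n, greg) - 1.0) * K[j] * d1[n - j];
    }
    const double d2_part = (-2.0 * g[n] + g[n - 1]) / h2;
    const double d1_part = -g[n - 1] / (2.0 * h);
    const double w0 = wt(0, n, greg);
    const double r0 = -d2_part - a * d1_part - K[n] * g[0] -
                      h * (s + w0 * K[0] * d1_part);
    const double coef = -(1.0 / h2 + a / (2.0 * h) + w0 * K[0] / 2.0);
    g[n + 1] = -r0 / coef;
    d1[n] = (g[n + 1] - g[n - 1]) / (2.0 * h);
  }
  return NumericVector(g.begin(), g.end());
}
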