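#include <RcppArmadillo.h>
#include <cmath>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline int wrap_index(int i, int n) {
  int r = i % n;
  return r < 0 ? r + n : r;
}

// Kaiser-Bessel kernel, support |u| <= halfw (grid units)
static inline double kb_exact(double t, double beta, double i0beta) {
  const double a = 1.0 - t * t;
  if (a <= 0.0) return 0.0;
  return std::cyl_bessel_i(0.0, beta * std::sqrt(a)) / i0beta;
}

// cached fine lookup table of the kernel over t = u/halfw in [0, 1];
// 1/32768 spacing keeps the linear-interpolation error ~1e-8, well below
// the kernel's own aliasing error
struct KbTable {
  double beta = -1.0;
  std::vector<double> tab;
  static const int n = 32768;
  void ensure(double b, double i0b) {
    if (b == beta) return;
    beta = b;
    tab.resize(n + 2);
    for (int i = 0; i <= n + 1; ++i) {
      tab[i] = kb_exact(std::min(1.0, (double)i / n), b, i0b);
    }
  }
  inline double operator()(double t) const {
    const double a = std::abs(t);
    if (a >= 1.0) return 0.0;
    const double s = a * n;
    const int i = (int)s;
    const double f = s - i;
    return tab[i] * (1.0 - f) + tab[i + 1] * f;
  }
};

static KbTable kb_table;

static inline double kb_weight(double u, double halfw, double beta, double i0beta) {
  (void)beta; (void)i0beta;
  return kb_table(u / halfw);
}

// Spread non-uniform samples onto an oversampled Cartesian grid (adjoint
// gridding step). s is (nsamp x nchannel); gy, gx are fractional grid
// coordinates in [0, ng) with periodic wrap-around. Returns (ng, ng, nch).
// [[Rcpp::export(name = ".kb_spread_2d")]]
arma::cx_cube kb_spread_2d(const arma::cx_mat& s, const arma::vec& gy,
                           const arma::vec& gx, const int ng, const int width,
                           const double beta) {
  const uword nsamp = s.n_rows, nch = s.n_cols;
  const double halfw = width / 2.0;
  const double i0b = std::cyl_bessel_i(0.0, beta);
  kb_table.ensure(beta, i0b);
  cx_cube grid(ng, ng, nch, fill::zeros);
  std::vector<double> wy(width + 2), wx(width + 2);
  std::vector<int> iy(width + 2), ix(width + 2);
  for (uword m = 0; m < nsamp; ++m) {
    const double cy = gy[m], cx = gx[m];
    int nyk = 0, nxk = 0;
    const int y0 = (int)std::ceil(cy - halfw), y1 = (int)std::floor(cy + halfw);
    const int x0 = (int)std::ceil(cx - halfw), x1 = (int)std::floor(cx + halfw);
    for (int p = y0; p <= y1; ++p) {
      const double w = kb_weight(cy - p, halfw, beta, i0b);
      if (w > 0.0) { wy[nyk] = w; iy[nyk++] = wrap_index(p, ng); }
    }
    for (int p = x0; p <= x1; ++p) {
      const double w = kb_weight(cx - p, halfw, beta, i0b);
      if (w > 0.0) { wx[nxk] = w; ix[nxk++] = wrap_index(p, ng); }
    }
    for (uword ch = 0; ch < nch; ++ch) {
      const std::complex<double> v = s(m, ch);
      for (int b = 0; b < nxk; ++b) {
        const std::complex<double> vx = v * wx[b];
        const int col = ix[b];
        for (int a = 0; a < nyk; ++a) grid(iy[a], col, ch) += vx * wy[a];
      }
    }
  }
  return grid;
}

// Interpolate grid values at non-uniform points (forward gridding step);
// exact transpose of kb_spread_2d. Returns (nsamp x nch).
// [[Rcpp::export(name = ".kb_interp_2d")]]
arma::cx_mat kb_interp_2d(const arma::cx_cube& grid, const arma::vec& gy,
                          const arma::vec& gx, const int width,
                          const double beta) {
  const uword nsamp = gy.n_elem, nch = grid.n_slices;
  const int ng = grid.n_rows;
  const double halfw = width / 2.0;
  const double i0b = std::cyl_bessel_i(0.0, beta);
  kb_table.ensure(beta, i0b);
  cx_mat out(nsamp, nch, fill::zeros);
  std::vector<double> wy(width + 2), wx(width + 2);
  std::vector<int> iy(width + 2), ix(width + 2);
  for (uword m = 0; m < nsamp; ++m) {
    const double cy = gy[m], cx = gx[m];
    int nyk = 0, nxk = 0;
    const int y0 = (int)std::ceil(cy - halfw), y1 = (int)std::floor(cy + halfw);
    const int x0 = (int)std::ceil(cx - halfw), x1 = (int)std::floor(cx + halfw);
    for (int p = y0; p <= y1; ++p) {
      const double w = kb_weight(cy - p, halfw, beta, i0b);
      if (w > 0.0) { wy[nyk] = w; iy[nyk++] = wrap_index(p, ng); }
    }
    for (int p = x0; p <= x1; ++p) {
      const double w = kb_weight(cx - p, halfw, beta, i0b);
      if (w > 0.0) { wx[nxk] = w; ix[nxk++] = wrap_index(p, ng); }
    }
    for (uword ch = 0; ch < nch; ++ch) {
      std::complex<double> acc(0.0, 0.0);
      for (int b = 0; b < nxk; ++b) {
        const int col = ix[b];
        std::complex<double> accy(0.0, 0.0);
        for (int a = 0; a < nyk; ++a) accy += grid(iy[a], col, ch) * wy[a];
        acc += accy * wx[b];
      }
      out(m, ch) = acc;
    }
  }
  return out;
}

// Exact 1D total-variation proximal operator (Condat's direct algorithm):
// x = argmin 0.5*||x - y||^2 + lam * sum |x_{i+1} - x_i|
static void tv1d_condat(const double* y, double* x, const int n,
                        const double lam) {
  if (n <= 0) return;
  if (n == 1 || lam <= 0.0) {
    for (int i = 0; i < n; ++i) x[i] = y[i];
    return;
  }
  int k = 0, k0 = 0, km = 0, kp = 0;
  double vmin = y[0] - lam, vmax = y[0] + lam, umin = lam, umax = -lam;
  for (;;) {
    if (k == n - 1) {
      if (umin < 0.0) {
        for (int i = k0; i <= km; ++i) x[i] = vmin;
        k0 = km + 1;
        k = km = k0;
        vmin = y[k];
        umin = lam;
        umax = y[k] + lam - vmax;
      } else if (umax > 0.0) {
        for (int i = k0; i <= kp; ++i) x[i] = vmax;
        k0 = kp + 1;
        k = kp = k0;
        vmax = y[k];
        umax = -lam;
        umin = y[k] - lam - vmin;
      } else {
        const double v = vmin + umin / (k - k0 + 1);
        for (int i = k0; i <= k; ++i) x[i] = v;
        return;
      }
      if (k > n - 1) return;  // defensive; should not trigger
    } else {
      if (y[k + 1] + umin < vmin - lam) {  // negative jump forced
        for (int i = k0; i <= km; ++i) x[i] = vmin;
        k = k0 = km = kp = km + 1;
        vmin = y[k];
        vmax = y[k] + 2.0 * lam;
        umin = lam;
        umax = -lam;
      } else if (y[k + 1] + umax > vmax + lam) {  // positive jump forced
        for (int i = k0; i <= kp; ++i) x[i] = vmax;
        k = k0 = km = kp = kp + 1;
        vmin = y[k] - 2.0 * lam;
        vmax = y[k];
        umin = lam;
        umax = -lam;
      } else {  // extend current segment
        ++k;
        umin += y[k] - vmin;
        umax += y[k] - vmax;
        if (umin >= lam) {
          vmin += (umin - lam) / (k - k0 + 1);
          umin = lam;
          km = k;
        }
        if (umax <= -lam) {
          vmax += (umax + lam) / (k - k0 + 1);
          umax = -lam;
          kp = k;
        }
      }
    }
  }
}

// Columnwise 1D TV prox; used for the temporal total-variation proximal step
// with columns = voxels and rows = frames.
// [[Rcpp::export(name = ".tv1d_prox_cols")]]
arma::mat tv1d_prox_cols(const arma::mat& y, const double lam) {
  mat x(y.n_rows, y.n_cols);
  const int n = y.n_rows;
  for (uword j = 0; j < y.n_cols; ++j) {
    tv1d_condat(y.colptr(j), x.colptr(j), n, lam);
  }
  return x;
}
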