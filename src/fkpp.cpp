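// Right-hand side of the generalized FKPP equation on a rectangular grid:
//   du/dt = D * Lap9(u) + k(x) * u * (1 - u)
// with the nine-point Laplacian
//   Lap9 u = [-20 u + sum(corners) + 4 sum(edges)] / (6 h^2),
// periodic boundaries along x (lateral), and clamped rows along y
// (du/dt = 0 on the first n_clamp_lo and last n_clamp_hi columns, which the
// integrator keeps at 1 and 0 respectively).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// context for the deSolve compiled-function interface (single-threaded)
static std::vector<double> g_kmap;
static double g_D = 0, g_h = 1;
static int g_nx = 0, g_ny = 0, g_clo = 0, g_chi = 0;

// [[Rcpp::export]]
void fkpp_set_ctx(NumericVector kmap, double D, double h, int nx, int ny,
                  int n_clamp_lo, int n_clamp_hi) {
  g_kmap.assign(kmap.begin(), kmap.end());
  g_D = D; g_h = h; g_nx = nx; g_ny = ny;
  g_clo = n_clamp_lo; g_chi = n_clamp_hi;
}

extern "C" void fkpp_deriv_c(int* neq, double* t, double* y, double* ydot,
                             double* yout, int* ip) {
  const int nx = g_nx, ny = g_ny;
  const double inv6h2 = 1.0 / (6.0 * g_h * g_h);
  for (int i = 0; i < nx * ny; ++i) ydot[i] = 0.0;
  for (int iy = g_clo; iy < ny - g_chi; ++iy) {
    const int ym = (iy - 1) * nx, y0 = iy * nx, yp = (iy + 1) * nx;
    for (int ix = 0; ix < nx; ++ix) {
      const int xm = (ix == 0) ? nx - 1 : ix - 1;
      const int xp = (ix == nx - 1) ? 0 : ix + 1;
      const double c = y[y0 + ix];
      const double lap = (-20.0 * c
        + (y[ym + xm] + y[ym + xp] + y[yp + xm] + y[yp + xp])
        + 4.0 * (y[ym + ix] + y[yp + ix] + y[y0 + xm] + y[y0 + xp])) * inv6h2;
      ydot[y0 + ix] = g_D * lap + g_kmap[y0 + ix] * c * (1.0 - c);
    }
  }
}

// [[Rcpp::export]]
NumericVector fkpp_rhs_cpp(NumericVector u, NumericVector kmap,
                           double D, double h, int nx, int ny,
                           int n_clamp_lo, int n_clamp_hi) {
  if ((int)u.size() != nx * ny) stop("state length does not match grid");
  NumericVector du(nx * ny);
  const double inv6h2 = 1.0 / (6.0 * h * h);
  for (int iy = n_clamp_lo; iy < ny - n_clamp_hi; ++iy) {
    const int ym = (iy - 1) * nx, y0 = iy * nx, yp = (iy + 1) * nx;
    for (int ix = 0; ix < nx; ++ix) {
      const int xm = (ix == 0) ? nx - 1 : ix - 1;
      const int xp = (ix == nx - 1) ? 0 : ix + 1;
      const double c = u[y0 + ix];
      const double lap = (-20.0 * c
        + (u[ym + xm] + u[ym + xp] + u[yp + xm] + u[yp + xp])
        + 4.0 * (u[ym + ix] + u[yp + ix] + u[y0 + xm] + u[y0 + xp])) * inv6h2;
      du[y0 + ix] = D * lap + kmap[y0 + ix] * c * (1.0 - c);
    }
  }
  return du;
}

// Nine-point Laplacian of a matrix on interior cells exactly as printed;
// boundary cells are returned as NA.
// [[Rcpp::export]]
NumericMatrix nine_point_lap_cpp(NumericMatrix u, double h) {
  const int nr = u.nrow(), nc = u.ncol();
  if (nr < 3 || nc < 3) stop("grid must be at least 3 x 3");
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), NA_REAL);
  const double inv6h2 = 1.0 / (6.0 * h * h);
  for (int j = 1; j < nc - 1; ++j)
    for (int i = 1; i < nr - 1; ++i)
      out(i, j) = (-20.0 * u(i, j)
        + (u(i - 1, j - 1) + u(i - 1, j + 1) + u(i + 1, j - 1) + u(i + 1, j + 1))
        + 4.0 * (u(i - 1, j) + u(i + 1, j) + u(i, j - 1) + u(i, j + 1))) * inv6h2;
  return out;
}
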