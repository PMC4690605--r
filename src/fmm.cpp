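// Fast-marching solver for the constant-speed (eikonal) model:
// |grad T| = 1/v on a rectangular grid, T = 0 on an initial front row,
// obstacle cells excluded (T = +Inf).  Upwind discretization is second
// order where two known neighbors are available (order = 2, default),
// falling back to first order; order = 1 forces the plain scheme.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

struct HeapEntry {
  double t;
  int idx;
  bool operator>(const HeapEntry& o) const { return t > o.t; }
};

const double INF = std::numeric_limits<double>::infinity();

// One axis contribution: value b entering the quadratic as a*(T-b)^2,
// a = (coef/h)^2 with coef 1 (first order) or 3/2 (second order, b adjusted).
struct AxisTerm {
  bool ok;
  double a;
  double b;
  double t1; // smaller known neighbor value, for the causality check
};

inline AxisTerm axis_term(const std::vector<double>& T,
                          const std::vector<signed char>& known,
                          int i, int n_axis, int stride, int nx, int ny,
                          bool is_x, double h, int order) {
  AxisTerm out{false, 0.0, 0.0, 0.0};
  int ia = is_x ? (i % nx) : (i / nx);
  double best = INF;
  int dir = 0;
  for (int s = -1; s <= 1; s += 2) {
    int j = ia + s;
    if (j < 0 || j >= n_axis) continue;
    int nb = i + s * stride;
    if (known[nb] && T[nb] < best) { best = T[nb]; dir = s; }
  }
  if (!std::isfinite(best)) return out;
  out.ok = true;
  out.t1 = best;
  if (order >= 2) {
    int j2 = ia + 2 * dir;
    if (j2 >= 0 && j2 < n_axis) {
      int nb2 = i + 2 * dir * stride;
      if (known[nb2] && T[nb2] <= best) {
        double tt = (4.0 * best - T[nb2]) / 3.0;
        out.a = (1.5 / h) * (1.5 / h);
        out.b = tt;
        return out;
      }
    }
  }
  out.a = 1.0 / (h * h);
  out.b = best;
  return out;
}

// Solve sum_i a_i (T - b_i)^2 = rhs2 for the largest root, requiring
// causality T >= max(t1).  Returns INF if no valid solution.
inline double solve_update(const AxisTerm& ax, const AxisTerm& ay, double rhs2) {
  double cand = INF;
  if (ax.ok && ay.ok) {
    double A = ax.a + ay.a;
    double B = -2.0 * (ax.a * ax.b + ay.a * ay.b);
    double C = ax.a * ax.b * ax.b + ay.a * ay.b * ay.b - rhs2;
    double disc = B * B - 4.0 * A * C;
    if (disc >= 0.0) {
      double t = (-B + std::sqrt(disc)) / (2.0 * A);
      if (t >= ax.t1 && t >= ay.t1) cand = t;
    }
  }
  if (!std::isfinite(cand)) {
    // one-sided updates
    if (ax.ok) cand = std::min(cand, ax.b + std::sqrt(rhs2 / ax.a));
    if (ay.ok) cand = std::min(cand, ay.b + std::sqrt(rhs2 / ay.a));
  }
  return cand;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix fmm_solve_cpp(LogicalMatrix blocked, double h, double v,
                            int init_col, int order) {
  const int nx = blocked.nrow();  // lateral (x) index
  const int ny = blocked.ncol();  // propagation (y) index
  if (init_col < 1 || init_col > ny)
    stop("initial front column outside grid");
  const int j0 = init_col - 1;
  const double rhs2 = 1.0 / (v * v);

  std::vector<double> T(static_cast<size_t>(nx) * ny, INF);
  std::vector<signed char> known(static_cast<size_t>(nx) * ny, 0);
  std::priority_queue<HeapEntry, std::vector<HeapEntry>, std::greater<HeapEntry>> heap;

  auto blk = [&](int i) { return blocked[i] != 0; };

  for (int ix = 0; ix < nx; ++ix) {
    int i = j0 * nx + ix;
    if (!blk(i)) {
      T[i] = 0.0;
      heap.push({0.0, i});
    }
  }

  const int dx[4] = {1, -1, 0, 0};
  const int dy[4] = {0, 0, 1, -1};

  while (!heap.empty()) {
    HeapEntry e = heap.top();
    heap.pop();
    if (known[e.idx]) continue;          // stale duplicate
    if (e.t > T[e.idx]) continue;
    known[e.idx] = 1;
    int ix = e.idx % nx, iy = e.idx / nx;
    for (int k = 0; k < 4; ++k) {
      int jx = ix + dx[k], jy = iy + dy[k];
      if (jx < 0 || jx >= nx || jy < 0 || jy >= ny) continue;
      int nb = jy * nx + jx;
      if (known[nb] || blk(nb)) continue;
      AxisTerm ax = axis_term(T, known, nb, nx, 1, nx, ny, true, h, order);
      AxisTerm ay = axis_term(T, known, nb, ny, nx, nx, ny, false, h, order);
      double t = solve_update(ax, ay, rhs2);
      if (t < T[nb]) {
        T[nb] = t;
        heap.push({t, nb});
      }
    }
  }

  NumericMatrix out(nx, ny);
  for (size_t i = 0; i < T.size(); ++i) out[i] = T[i];
  for (int i = 0; i < nx * ny; ++i)
    if (blocked[i]) out[i] = R_PosInf;
  return out;
}
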