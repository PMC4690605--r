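// Stochastic Eden growth on a hexagonal lattice ("pointy-top" offset layout,
// odd rows shifted by half a lattice unit to the right).  One individual per
// site; a uniformly chosen frontier site (occupied, >= 1 empty neighbor)
// copies its genotype into a uniformly chosen empty neighbor; time advances
// by Exp(mean = 1 / |frontier|) evaluated before the event.  Blocked sites
// (obstacles + side walls) never change state and are never chosen.
// Uses R's RNG stream so set.seed() makes runs reproducible.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

// neighbor offsets for offset-hex rows: even rows use (dr, dc) with
// up/down columns {c-1, c}; odd rows use {c, c+1}.
inline int n_neighbors(int r, int c, int nrow, int ncol,
                       int* nbr, const int ncol_stride) {
  int cnt = 0;
  const int base = r * ncol_stride;
  if (c > 0)        nbr[cnt++] = base + c - 1;
  if (c < ncol - 1) nbr[cnt++] = base + c + 1;
  const int off = (r % 2 == 0) ? -1 : 0;
  for (int dr = -1; dr <= 1; dr += 2) {
    int rr = r + dr;
    if (rr < 0 || rr >= nrow) continue;
    for (int k = 0; k <= 1; ++k) {
      int cc = c + off + k;
      if (cc < 0 || cc >= ncol) continue;
      nbr[cnt++] = rr * ncol_stride + cc;
    }
  }
  return cnt;
}

} // namespace

// [[Rcpp::export]]
List eden_run_cpp(IntegerVector init_state, int nrow, int ncol,
                  int stop_row, int max_events) {
  // init_state: length nrow*ncol, row-major (index r*ncol + c);
  // -1 blocked, 0 empty, > 0 genotype id (initial occupied sites).
  const int n = nrow * ncol;
  if ((int)init_state.size() != n) stop("state length mismatch");
  if (stop_row < 0 || stop_row >= nrow) stop("stop_row outside lattice");

  std::vector<int> state(init_state.begin(), init_state.end());
  std::vector<int> parent(n, 0);        // 1-based site index, 0 = founder/none
  std::vector<double> btime(n, NA_REAL);
  std::vector<int> frontier;            // site indices
  std::vector<int> pos(n, -1);          // position in frontier, -1 = absent
  std::vector<int> empty_per_row(nrow, 0);

  int nbr[6], nbr2[6];

  int n_empty = 0;
  for (int r = 0; r < nrow; ++r)
    for (int c = 0; c < ncol; ++c) {
      int i = r * ncol + c;
      if (state[i] == 0) { ++empty_per_row[r]; ++n_empty; }
      if (state[i] > 0) btime[i] = 0.0;
    }

  auto has_empty = [&](int i) {
    int r = i / ncol, c = i % ncol;
    int m = n_neighbors(r, c, nrow, ncol, nbr2, ncol);
    for (int k = 0; k < m; ++k) if (state[nbr2[k]] == 0) return true;
    return false;
  };
  auto frontier_add = [&](int i) {
    if (pos[i] < 0) { pos[i] = frontier.size(); frontier.push_back(i); }
  };
  auto frontier_remove = [&](int i) {
    int p = pos[i];
    if (p < 0) return;
    int last = frontier.back();
    frontier[p] = last; pos[last] = p;
    frontier.pop_back(); pos[i] = -1;
  };

  for (int i = 0; i < n; ++i)
    if (state[i] > 0 && has_empty(i)) frontier_add(i);

  int rows_pending = 0;
  for (int r = 0; r <= stop_row; ++r) if (empty_per_row[r] > 0) ++rows_pending;

  if (max_events < 0 || max_events > n_empty) max_events = n_empty;
  std::vector<int> ev_parent, ev_child, ev_nf;
  std::vector<double> ev_time;
  ev_parent.reserve(max_events); ev_child.reserve(max_events);
  ev_time.reserve(max_events); ev_nf.reserve(max_events);

  double t = 0.0;
  int status = 3; // 0 stop_row filled, 1 absorbed, 2 reached top row, 3 max_events
  int n_events = 0;

  while (n_events < max_events) {
    if (rows_pending == 0) { status = 0; break; }
    const int nF = (int)frontier.size();
    if (nF == 0) { status = 1; break; }
    t += R::exp_rand() / nF;
    int pick = (int)(R::unif_rand() * nF);
    if (pick >= nF) pick = nF - 1;
    const int site = frontier[pick];
    const int r = site / ncol, c = site % ncol;
    int m = n_neighbors(r, c, nrow, ncol, nbr, ncol);
    int empties[6], ne = 0;
    for (int k = 0; k < m; ++k) if (state[nbr[k]] == 0) empties[ne++] = nbr[k];
    // frontier invariant guarantees ne >= 1
    int pick2 = (int)(R::unif_rand() * ne);
    if (pick2 >= ne) pick2 = ne - 1;
    const int child = empties[pick2];

    state[child] = state[site];
    parent[child] = site + 1;
    btime[child] = t;
    const int rc = child / ncol;
    if (--empty_per_row[rc] == 0 && rc <= stop_row) --rows_pending;

    ev_parent.push_back(site + 1); ev_child.push_back(child + 1);
    ev_time.push_back(t); ev_nf.push_back(nF);
    ++n_events;

    // incremental frontier maintenance around the filled site
    if (has_empty(child)) frontier_add(child);
    const int cc = child % ncol;
    m = n_neighbors(rc, cc, nrow, ncol, nbr, ncol);
    for (int k = 0; k < m; ++k) {
      int nb = nbr[k];
      if (state[nb] > 0 && pos[nb] >= 0 && !has_empty(nb)) frontier_remove(nb);
    }
    if (rc == nrow - 1) { status = 2; break; }
  }

  std::vector<int> frontier_sites(frontier.begin(), frontier.end());
  for (auto& x : frontier_sites) x += 1;

  return List::create(
    _["state"] = IntegerVector(state.begin(), state.end()),
    _["parent"] = IntegerVector(parent.begin(), parent.end()),
    _["btime"] = NumericVector(btime.begin(), btime.end()),
    _["ev_parent"] = IntegerVector(ev_parent.begin(), ev_parent.end()),
    _["ev_child"] = IntegerVector(ev_child.begin(), ev_child.end()),
    _["ev_time"] = NumericVector(ev_time.begin(), ev_time.end()),
    _["ev_frontier_size"] = IntegerVector(ev_nf.begin(), ev_nf.end()),
    _["n_events"] = n_events,
    _["final_time"] = t,
    _["frontier"] = IntegerVector(frontier_sites.begin(), frontier_sites.end()),
    _["status"] = status);
}
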