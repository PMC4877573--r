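#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Corrosion cellular automaton: synchronous update of an integer state
// grid.  For each cell, d = state - min(8-connected in-grid neighbors);
// if d > v the cell loses C = floor(gamma * d) units of state and C is
// added to the iteration's corroded mass.
//
// The neighborhood minimum is computed separably (vertical 3-min, then
// horizontal 3-min), which yields the min over the full 3x3 block
// including the center.  That is equivalent for the update: when the
// block min is attained only at the center, all neighbors are >= the
// center, so d <= 0 <= v either way and the cell does not corrode.
//
// Returns the final grid and the cumulative mass after each of the
// `iters` iterations.  Once an iteration corrodes nothing the automaton
// is at a fixed point and the remaining entries are filled directly.
// [[Rcpp::export]]
List cita_run(IntegerMatrix grid, double v, double gamma, int iters) {
  int M = grid.nrow(), N = grid.ncol();
  IntegerMatrix cur(clone(grid));
  std::vector<int> vmin((size_t)M * N);
  NumericVector mass(iters);
  double total = 0.0;
  int* g = INTEGER(cur);

  for (int t = 0; t < iters; ++t) {
    double inc = 0.0;
    // vertical 3-min within each column (clamped at borders)
    for (int j = 0; j < N; ++j) {
      const int* col = g + (size_t)j * M;
      int* vm = vmin.data() + (size_t)j * M;
      if (M == 1) { vm[0] = col[0]; continue; }
      vm[0] = col[0] < col[1] ? col[0] : col[1];
      for (int i = 1; i < M - 1; ++i) {
        int m = col[i - 1] < col[i] ? col[i - 1] : col[i];
        vm[i] = m < col[i + 1] ? m : col[i + 1];
      }
      vm[M - 1] = col[M - 2] < col[M - 1] ? col[M - 2] : col[M - 1];
    }
    // horizontal 3-min across columns + corrosion update
    for (int j = 0; j < N; ++j) {
      const int* vl = vmin.data() + (size_t)(j > 0 ? j - 1 : j) * M;
      const int* vc = vmin.data() + (size_t)j * M;
      const int* vr = vmin.data() + (size_t)(j < N - 1 ? j + 1 : j) * M;
      int* col = g + (size_t)j * M;
      for (int i = 0; i < M; ++i) {
        int m = vl[i] < vc[i] ? vl[i] : vc[i];
        if (vr[i] < m) m = vr[i];
        int d = col[i] - m;
        if (d > v) {
          int C = (int)std::floor(gamma * (double)d);
          col[i] -= C;
          inc += C;
        }
      }
    }
    total += inc;
    mass[t] = total;
    if (inc == 0.0) {
      for (int u = t + 1; u < iters; ++u) mass[u] = total;
      break;
    }
  }
  return List::create(_["grid"] = cur, _["mass"] = mass);
}
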