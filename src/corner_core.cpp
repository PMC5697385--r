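#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>

using namespace Rcpp;

// Minimum-cost assignment on a square cost matrix (shortest augmenting
// paths with dual potentials, O(n^3)). Returns, for each row, the 1-based
// column assigned to it. Costs must be finite.
// [[Rcpp::export]]
IntegerVector cpp_solve_assignment(NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n)
    stop("cost matrix must be square");
  if (n == 0)
    return IntegerVector(0);

  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);

  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else          minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }

  IntegerVector assign(n);
  for (int j = 1; j <= n; ++j)
    assign[p[j] - 1] = j;
  return assign;
}

// 8-connected component labelling of a logical matrix (edge chains are
// diagonal, so 4-connectivity would shatter contours).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<int> q;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!x(i, j) || lab(i, j)) continue;
      lab(i, j) = ++next;
      q.push(j * nr + i);
      while (!q.empty()) {
        int idx = q.front(); q.pop();
        int ci = idx % nr, cj = idx / nr;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int ii = ci + di, jj = cj + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (x(ii, jj) && !lab(ii, jj)) {
              lab(ii, jj) = next;
              q.push(jj * nr + ii);
            }
          }
      }
    }
  return lab;
}

// Hysteresis edge linking: keep candidate (weak) pixels that are
// 8-connected, through other candidates, to at least one strong pixel.
// Both inputs are logical matrices of equal dimension; strong is assumed
// to be a subset of cand.
// [[Rcpp::export]]
LogicalMatrix cpp_hysteresis(LogicalMatrix cand, LogicalMatrix strong) {
  const int nr = cand.nrow(), nc = cand.ncol();
  if (strong.nrow() != nr || strong.ncol() != nc)
    stop("cand and strong must have identical dimensions");

  LogicalMatrix out(nr, nc);
  std::vector<char> seen((size_t)nr * nc, 0);
  std::queue<int> q;

  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (strong(i, j) && cand(i, j)) {
        int idx = j * nr + i;
        if (!seen[idx]) { seen[idx] = 1; q.push(idx); }
      }
    }

  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int i = idx % nr, j = idx / nr;
    out(i, j) = true;
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0) continue;
        int ii = i + di, jj = j + dj;
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        if (!cand(ii, jj)) continue;
        int nidx = jj * nr + ii;
        if (!seen[nidx]) { seen[nidx] = 1; q.push(nidx); }
      }
  }
  return out;
}
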