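// Grid solvers: first-order fast marching (eikonal arrival times on a masked
// lattice) and an exact Euclidean distance transform (coastal buffering).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

struct HeapNode {
  double t;
  int idx;
  bool operator>(const HeapNode& other) const { return t > other.t; }
};

// One-cell upwind update from accepted horizontal/vertical neighbour values.
// Solves max(D^-x T, -D^+x T, 0)^2 + max(D^-y T, -D^+y T, 0)^2 = h^2 at unit
// speed: quadratic solve when both directions contribute, one-sided otherwise.
inline double upwind_solve(double th, double tv, double h) {
  if (!std::isfinite(th) && !std::isfinite(tv)) return INF;
  double a = std::min(th, tv), b = std::max(th, tv);
  if (b - a >= h || !std::isfinite(b)) return a + h;
  double diff = b - a;
  return 0.5 * (a + b) + 0.5 * std::sqrt(2.0 * h * h - diff * diff);
}

} // namespace

// Single-front fast marching at unit speed from seed cells (0-based indices),
// spacing h (km). mask TRUE = traversable. Returns list(arrival, pop_order):
// arrival in km (Inf unreachable/masked), pop_order the sequence of accepted
// arrival values (to assert heap causality in tests).
// [[Rcpp::export(name = ".fmm_solve")]]
List fmm_solve(LogicalMatrix mask, IntegerVector seed_row, IntegerVector seed_col,
               double h, bool record_order = false) {
  const int nr = mask.nrow(), nc = mask.ncol(), n = nr * nc;
  NumericMatrix arrival(nr, nc);
  std::vector<char> known(n, 0);
  std::fill(arrival.begin(), arrival.end(), INF);
  std::priority_queue<HeapNode, std::vector<HeapNode>, std::greater<HeapNode> > heap;
  std::vector<double> pops;

  for (int k = 0; k < seed_row.size(); ++k) {
    int r = seed_row[k], c = seed_col[k];
    if (r < 0 || r >= nr || c < 0 || c >= nc)
      stop("seed cell outside the grid");
    if (!mask(r, c)) stop("seed cell is not traversable");
    arrival(r, c) = 0.0;
    heap.push({0.0, r + c * nr});
  }

  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};

  while (!heap.empty()) {
    HeapNode nd = heap.top();
    heap.pop();
    int idx = nd.idx;
    if (known[idx]) continue;          // stale heap entry
    known[idx] = 1;
    if (record_order) pops.push_back(nd.t);
    int r = idx % nr, c = idx / nr;
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (!mask(rr, cc) || known[rr + cc * nr]) continue;
      double th = INF, tv = INF;
      if (cc > 0 && known[rr + (cc - 1) * nr]) th = arrival(rr, cc - 1);
      if (cc < nc - 1 && known[rr + (cc + 1) * nr])
        th = std::min(th, arrival(rr, cc + 1));
      if (rr > 0 && known[rr - 1 + cc * nr]) tv = arrival(rr - 1, cc);
      if (rr < nr - 1 && known[rr + 1 + cc * nr])
        tv = std::min(tv, arrival(rr + 1, cc));
      double t = upwind_solve(th, tv, h);
      if (t < arrival(rr, cc)) {
        arrival(rr, cc) = t;
        heap.push({t, rr + cc * nr});
      }
    }
  }

  return List::create(_["arrival"] = arrival,
                      _["pop_order"] = NumericVector(pops.begin(), pops.end()));
}

namespace {

// Felzenszwalb & Huttenlocher 1D squared distance transform.
void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

} // namespace

// Exact Euclidean distance (km) from every cell centre to the nearest TRUE
// cell centre, for cell spacing h.
// [[Rcpp::export(name = ".edt_km")]]
NumericMatrix edt_km(LogicalMatrix feature, double h) {
  const int nr = feature.nrow(), nc = feature.ncol();
  // finite sentinel for "no feature in reach" keeps the envelope
  // intersections well defined (INF - INF is NaN)
  const double BIG = 1e12;
  NumericMatrix sq(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      sq(i, j) = feature(i, j) ? 0.0 : BIG;

  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int j = 0; j < nc; ++j) {              // along rows (columns fixed)
    for (int i = 0; i < nr; ++i) f[i] = sq(i, j);
    dt1d(f, d, nr);
    for (int i = 0; i < nr; ++i) sq(i, j) = d[i];
  }
  for (int i = 0; i < nr; ++i) {              // along columns
    for (int j = 0; j < nc; ++j) f[j] = sq(i, j);
    dt1d(f, d, nc);
    for (int j = 0; j < nc; ++j) sq(i, j) = d[j];
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      sq(i, j) = (sq(i, j) >= BIG) ? INF : h * std::sqrt(sq(i, j));
  return sq;
}
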