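#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Cost-distance accumulation over a raster: Dijkstra on the implicit
// 8- (or 4-) neighbour graph with the standard cost-distance transition
// ((cm[a] + cm[b]) / 2, times sqrt(2) for diagonal moves), in cell units.
// Backlink codes 1..8 give the direction (N, NE, E, SE, S, SW, W, NW)
// from a cell towards its predecessor on an optimal route to a source;
// 0 marks sources and unreached cells. Tie-breaking is deterministic:
// equal accumulated costs resolve by queue insertion order, and
// neighbours are relaxed in the fixed N, NE, E, SE, S, SW, W, NW order.

struct QItem {
  double dist;
  unsigned long long stamp;
  int idx;
};
struct QCmp {
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.dist != b.dist) return a.dist > b.dist;
    return a.stamp > b.stamp;
  }
};

// [[Rcpp::export]]
List cpp_accumulate(NumericMatrix cm, IntegerVector src_rows,
                    IntegerVector src_cols, bool diagonal = true) {
  const int nr = cm.nrow(), nc = cm.ncol();
  // neighbour order: N, NE, E, SE, S, SW, W, NW (row 1 = north)
  const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  const double SQ2 = std::sqrt(2.0);

  NumericMatrix acc(nr, nc);
  IntegerMatrix back(nr, nc);
  std::vector<bool> done((size_t)nr * nc, false);
  std::fill(acc.begin(), acc.end(), R_PosInf);
  std::fill(back.begin(), back.end(), 0);

  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  unsigned long long stamp = 0;

  for (int k = 0; k < src_rows.size(); ++k) {
    int r = src_rows[k] - 1, c = src_cols[k] - 1;
    if (r < 0 || r >= nr || c < 0 || c >= nc)
      stop("source cell outside grid");
    if (NumericMatrix::is_na(cm(r, c)))
      stop("source cell lies on nodata");
    if (acc(r, c) > 0) {
      acc(r, c) = 0.0;
      pq.push({0.0, stamp++, r + c * nr});
    }
  }

  const int ndir = diagonal ? 8 : 8; // always scan 8; skip diagonals below
  while (!pq.empty()) {
    QItem it = pq.top();
    pq.pop();
    int idx = it.idx;
    if (done[idx]) continue;
    done[idx] = true;
    int r = idx % nr, c = idx / nr;
    double du = acc(r, c);
    double cu = cm(r, c);
    for (int i = 0; i < ndir; ++i) {
      bool diag = (i % 2 == 1);
      if (diag && !diagonal) continue;
      int r2 = r + dr[i], c2 = c + dc[i];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (NumericMatrix::is_na(cm(r2, c2))) continue;
      int idx2 = r2 + c2 * nr;
      if (done[idx2]) continue;
      double w = 0.5 * (cu + cm(r2, c2)) * (diag ? SQ2 : 1.0);
      double nd = du + w;
      if (nd < acc(r2, c2)) {
        acc(r2, c2) = nd;
        // direction from neighbour back to (r, c): opposite of i
        back(r2, c2) = (i + 4) % 8 + 1;
        pq.push({nd, stamp++, idx2});
      }
    }
  }
  for (int i = 0; i < nr * nc; ++i)
    if (acc[i] == R_PosInf) acc[i] = NA_REAL;
  return List::create(_["acc"] = acc, _["backlink"] = back);
}
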