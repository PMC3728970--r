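#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Fixed neighbour scan order: N, NE, E, SE, S, SW, W, NW.
// Rows grow southward, columns eastward; matrices are column-major (R layout).
static const int DR[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int DC[8] = {0, 1, 1, 1, 0, -1, -1, -1};

// Multi-source Dijkstra over the 8-connected grid.
// Step cost between adjacent cells a,b: mean(resistance) * distance, with
// distance = cell_size (rook) or cell_size*sqrt(2) (diagonal).
// Cells with resistance >= barrier are impassable. Returns the accumulated
// cost grid (Inf where unreachable) and a predecessor grid (1-based linear
// index into the matrix, 0 for sources/unreached) for path backtracing.
// [[Rcpp::export]]
List grid_dijkstra(NumericMatrix resist, LogicalMatrix sources,
                   double cell_size, double barrier) {
  const int nr = resist.nrow(), nc = resist.ncol(), n = nr * nc;
  NumericMatrix cost(nr, nc);
  IntegerMatrix pred(nr, nc);
  std::fill(cost.begin(), cost.end(), R_PosInf);
  std::fill(pred.begin(), pred.end(), 0);

  typedef std::pair<double, int> QE; // (cost, linear index)
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;

  for (int i = 0; i < n; ++i) {
    if (sources[i] && resist[i] < barrier) {
      cost[i] = 0.0;
      pq.push(QE(0.0, i));
    }
  }

  const double diag = cell_size * std::sqrt(2.0);
  while (!pq.empty()) {
    const double d = pq.top().first;
    const int i = pq.top().second;
    pq.pop();
    if (d > cost[i]) continue; // stale entry
    const int r = i % nr, c = i / nr;
    const double ri = resist[i];
    for (int k = 0; k < 8; ++k) {
      const int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      const int j = rr + cc * nr;
      const double rj = resist[j];
      if (rj >= barrier) continue;
      const double step = 0.5 * (ri + rj) * ((DR[k] != 0 && DC[k] != 0) ? diag : cell_size);
      const double nd = d + step;
      if (nd < cost[j]) {
        cost[j] = nd;
        pred[j] = i + 1;
        pq.push(QE(nd, j));
      }
    }
  }
  return List::create(_["cost"] = cost, _["pred"] = pred);
}

// Connected-component labelling of a boolean grid (4- or 8-connectivity).
// Components are numbered 1..k in scan order; background cells get 0.
// [[Rcpp::export]]
IntegerMatrix grid_components(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int nnb = (connectivity == 4) ? 4 : 8;
  // rook moves first so the 4-connectivity prefix is valid
  static const int R4[8] = {-1, 0, 1, 0, -1, -1, 1, 1};
  static const int C4[8] = {0, 1, 0, -1, -1, 1, -1, 1};
  int next = 0;
  std::vector<int> stack;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      const int i0 = r0 + c0 * nr;
      if (!mask[i0] || lab[i0] != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i0);
      lab[i0] = next;
      while (!stack.empty()) {
        const int i = stack.back();
        stack.pop_back();
        const int r = i % nr, c = i / nr;
        for (int k = 0; k < nnb; ++k) {
          const int rr = r + R4[k], cc = c + C4[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          const int j = rr + cc * nr;
          if (mask[j] && lab[j] == 0) {
            lab[j] = next;
            stack.push_back(j);
          }
        }
      }
    }
  }
  return lab;
}

// Minimum Euclidean distance from each point to a set of line segments;
// returns distances and the 1-based index of the nearest segment.
// [[Rcpp::export]]
List pts_to_segments_min(NumericVector px, NumericVector py,
                         NumericVector x0, NumericVector y0,
                         NumericVector x1, NumericVector y1) {
  const int np = px.size(), ns = x0.size();
  NumericVector dist(np);
  IntegerVector which(np);
  for (int i = 0; i < np; ++i) {
    double best = R_PosInf;
    int bw = NA_INTEGER;
    for (int s = 0; s < ns; ++s) {
      const double dx = x1[s] - x0[s], dy = y1[s] - y0[s];
      const double L2 = dx * dx + dy * dy;
      double t = 0.0;
      if (L2 > 0.0) {
        t = ((px[i] - x0[s]) * dx + (py[i] - y0[s]) * dy) / L2;
        if (t < 0.0) t = 0.0;
        if (t > 1.0) t = 1.0;
      }
      const double ex = px[i] - (x0[s] + t * dx);
      const double ey = py[i] - (y0[s] + t * dy);
      const double d = std::sqrt(ex * ex + ey * ey);
      if (d < best) { best = d; bw = s + 1; }
    }
    dist[i] = best;
    which[i] = bw;
  }
  return List::create(_["dist"] = dist, _["which"] = which);
}

// Minimum Euclidean distance from each point to the nearest of a set of
// square cells (distance to the cell rectangle, 0 inside). Cells are given
// as 1-based (row, col) indices on a grid with top-left outer corner at
// (ox, oy), x east / y north.
// [[Rcpp::export]]
NumericVector pts_to_cells_min(NumericVector px, NumericVector py,
                               IntegerVector row, IntegerVector col,
                               double cell_size, double ox, double oy) {
  const int np = px.size(), nc = row.size();
  NumericVector out(np);
  const double h = 0.5 * cell_size;
  for (int i = 0; i < np; ++i) {
    double best = R_PosInf;
    for (int k = 0; k < nc; ++k) {
      const double cx = ox + (col[k] - 0.5) * cell_size;
      const double cy = oy - (row[k] - 0.5) * cell_size;
      double dx = std::fabs(px[i] - cx) - h;
      double dy = std::fabs(py[i] - cy) - h;
      if (dx < 0.0) dx = 0.0;
      if (dy < 0.0) dy = 0.0;
      const double d = std::sqrt(dx * dx + dy * dy);
      if (d < best) best = d;
      if (best == 0.0) break;
    }
    out[i] = best;
  }
  return out;
}
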