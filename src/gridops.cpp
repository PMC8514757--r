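#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>

using namespace Rcpp;

// Connected-component labeling of a logical matrix (BFS).
// connectivity = 4 or 8. Returns integer matrix, 0 outside mask.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nnb = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int r2 = rr + dr8[k], c2 = cc + dc8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && !lab(r2, c2)) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  return lab;
}

// Binary dilation with a disc of radius `radius` (in node units).
// [[Rcpp::export]]
LogicalMatrix cpp_dilate_disc(LogicalMatrix mask, double radius) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  int ir = (int)std::floor(radius);
  double r2 = radius * radius;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      for (int dc = -ir; dc <= ir; ++dc)
        for (int dr = -ir; dr <= ir; ++dr) {
          if (dr * dr + dc * dc > r2) continue;
          int r2i = r + dr, c2i = c + dc;
          if (r2i >= 0 && r2i < nr && c2i >= 0 && c2i < nc) out(r2i, c2i) = true;
        }
    }
  return out;
}

// Multi-source Dijkstra on a grid of conducting nodes; 8-connected with
// Euclidean step weights (h, h*sqrt(2)). Non-conducting nodes and paths
// through them are excluded. Returns distances, Inf where unreachable,
// NA where non-conducting.
// [[Rcpp::export]]
NumericMatrix cpp_grid_geodesic(LogicalMatrix conducting, IntegerVector src_r,
                                IntegerVector src_c, double h) {
  int nr = conducting.nrow(), nc = conducting.ncol();
  NumericMatrix dist(nr, nc);
  std::fill(dist.begin(), dist.end(), NA_REAL);
  const double INF = std::numeric_limits<double>::infinity();
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (conducting(r, c)) dist(r, c) = INF;
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (int i = 0; i < src_r.size(); ++i) {
    int r = src_r[i], c = src_c[i];
    if (r < 0 || r >= nr || c < 0 || c >= nc || !conducting(r, c))
      stop("geodesic source must be a conducting in-grid node");
    dist(r, c) = 0.0;
    pq.push(QE(0.0, r + c * nr));
  }
  int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  double sq2 = std::sqrt(2.0);
  while (!pq.empty()) {
    QE top = pq.top();
    pq.pop();
    int idx = top.second;
    int r = idx % nr, c = idx / nr;
    if (top.first > dist(r, c)) continue;
    for (int k = 0; k < 8; ++k) {
      int r2 = r + dr8[k], c2 = c + dc8[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (!conducting(r2, c2)) continue;
      double nd = top.first + (k < 4 ? h : h * sq2);
      if (nd < dist(r2, c2)) {
        dist(r2, c2) = nd;
        pq.push(QE(nd, r2 + c2 * nr));
      }
    }
  }
  return dist;
}
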