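#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

// 26-connected neighborhood offsets are generated on the fly; linear indices
// are 0-based column-major (x fastest), matching R array layout.

// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t seed = 0; seed < mask.size(); ++seed) {
    if (!mask[seed] || lab[seed]) continue;
    ++next;
    lab[seed] = next;
    stack.push_back(seed);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int x = cur % nx, y = (cur / nx) % ny, z = cur / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            R_xlen_t nb = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
            if (mask[nb] && !lab[nb]) { lab[nb] = next; stack.push_back(nb); }
          }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// Centrality-weighted shortest path: edge cost = step length / (d(target)+eps),
// so the path is drawn toward the lumen center where the distance map is large.
// Ties resolved lexicographically on linear voxel index via the queue ordering.
// [[Rcpp::export(name = ".center_path")]]
IntegerVector center_path(LogicalVector mask, NumericVector dmap,
                          IntegerVector dim, NumericVector spacing,
                          int start, int end, double eps) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = mask.size();
  std::vector<double> dist(n, R_PosInf);
  std::vector<R_xlen_t> parent(n, -1);
  typedef std::pair<double, R_xlen_t> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  dist[start] = 0.0;
  pq.push(Node(0.0, start));
  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    R_xlen_t cur = top.second;
    if (top.first > dist[cur]) continue;
    if (cur == end) break;
    int x = cur % nx, y = (cur / nx) % ny, z = cur / ((R_xlen_t)nx * ny);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          R_xlen_t nb = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
          if (!mask[nb]) continue;
          double step = std::sqrt(dx * dx * spacing[0] * spacing[0] +
                                  dy * dy * spacing[1] * spacing[1] +
                                  dz * dz * spacing[2] * spacing[2]);
          double w = step / (dmap[nb] + eps);
          double cand = dist[cur] + w;
          if (cand < dist[nb]) {
            dist[nb] = cand;
            parent[nb] = cur;
            pq.push(Node(cand, nb));
          }
        }
  }
  if (!R_finite(dist[end])) return IntegerVector(0);
  std::vector<int> path;
  for (R_xlen_t v = end; v != -1; v = parent[v]) path.push_back((int)v + 1);
  std::reverse(path.begin(), path.end());
  return wrap(path);
}
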