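#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// 3-D connected-component labelling with faces-only (6-neighbour)
// connectivity. mask is a logical array in column-major order with
// dimensions dim (length 3). Returns integer labels (0 = background),
// components numbered 1..n in discovery order.
// [[Rcpp::export(name = ".labelClusters6")]]
IntegerVector labelClusters6(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  IntegerVector labels(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next;
    stack.push_back(start);
    labels[start] = next;
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      const int nb[6][3] = {{x - 1, y, z}, {x + 1, y, z}, {x, y - 1, z},
                            {x, y + 1, z}, {x, y, z - 1}, {x, y, z + 1}};
      for (int q = 0; q < 6; ++q) {
        int xx = nb[q][0], yy = nb[q][1], zz = nb[q][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int w = xx + nx * (yy + ny * zz);
        if (mask[w] && labels[w] == 0) {
          labels[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}

// Size of the largest 6-connected component of mask (0 if empty).
// [[Rcpp::export(name = ".maxClusterSize6")]]
int maxClusterSize6(LogicalVector mask, IntegerVector dim) {
  IntegerVector labels = labelClusters6(mask, dim);
  int k = 0;
  for (int i = 0; i < labels.size(); ++i) k = std::max(k, labels[i]);
  if (k == 0) return 0;
  std::vector<int> counts(k + 1, 0);
  for (int i = 0; i < labels.size(); ++i) ++counts[labels[i]];
  counts[0] = 0;
  int best = 0;
  for (int c = 1; c <= k; ++c) best = std::max(best, counts[c]);
  return best;
}
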