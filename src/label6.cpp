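// 3D connected-component labeling with a 6-connectivity neighbourhood
// (face neighbours only). Labels are assigned in raster order of the first
// voxel of each component, so the labeling is deterministic.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector label6_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  if ((size_t)mask.size() != n) stop("mask size does not match dims");
  IntegerVector labels(mask.size(), 0);
  labels.attr("dim") = dims;
  std::vector<size_t> stack;
  int cur = 0;
  const size_t plane = (size_t)nx * ny;

  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++cur;
    labels[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      size_t p = stack.back(); stack.pop_back();
      int i = (int)(p % nx);
      int j = (int)((p / nx) % ny);
      int k = (int)(p / plane);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int q = 0; q < 6; ++q) {
        int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        size_t t = (size_t)kk * plane + (size_t)jj * nx + ii;
        if (mask[t] && labels[t] == 0) {
          labels[t] = cur;
          stack.push_back(t);
        }
      }
    }
  }
  return labels;
}
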