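// 26-connected component labelling of a binary 3D mask. Labels are assigned
// 1..K in raster-scan order of each component's first voxel, so the result is
// deterministic and independent of any RNG state.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".label_components26")]]
IntegerVector label_components26(IntegerVector mask) {
  IntegerVector d = mask.attr("dim");
  if (d.size() != 3) stop("mask must be 3D");
  const int nx = d[0], ny = d[1], nz = d[2];
  const long n = (long)nx * ny * nz;
  const long plane = (long)nx * ny;
  IntegerVector lab(n);
  lab.attr("dim") = d;
  int next = 0;
  std::vector<long> stack;
  for (long s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      long cur = stack.back(); stack.pop_back();
      int z = (int)(cur / plane);
      int rem = (int)(cur % plane);
      int y = rem / nx, x = rem % nx;
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz; if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy; if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = x + dx; if (xx < 0 || xx >= nx) continue;
            long q = (long)zz * plane + (long)yy * nx + xx;
            if (mask[q] != 0 && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
          }
        }
      }
    }
  }
  return lab;
}
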