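#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// 26-connected component labelling of a 3D logical mask.
// Returns an integer volume: 0 outside the mask, components numbered 1..K
// in order of first (column-major) encounter.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t c = stack.back();
      stack.pop_back();
      const int x = (int)(c % nx);
      const int y = (int)((c / nx) % ny);
      const int z = (int)(c / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz) {
        const int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            const int xx = x + dx;
            if (xx < 0 || xx >= nx || (dx == 0 && dy == 0 && dz == 0)) continue;
            const R_xlen_t q = (R_xlen_t)xx + nx * ((R_xlen_t)yy + (R_xlen_t)ny * zz);
            if (mask[q] && lab[q] == 0) {
              lab[q] = next;
              stack.push_back(q);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
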