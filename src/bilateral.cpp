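#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// mirror (reflect) index into [0, n-1]; period 2n-2 so the boundary voxel
// is not duplicated (symmetric half-sample-free reflection)
static inline int mirror(int i, int n) {
  if (n == 1) return 0;
  const int p = 2 * n - 2;
  i = i % p;
  if (i < 0) i += p;
  if (i >= n) i = p - i;
  return i;
}

// Joint bilateral filter of a co-registered pair of 3D volumes.
// One weight field per voxel, shared by both channels: the range term is
// the Euclidean distance over the 2-vector of per-channel HU differences,
// each scaled by its channel's range sigma.
// [[Rcpp::export]]
List joint_bf_cpp(NumericVector a, NumericVector b, IntegerVector dim,
                  double sigma_s, double sigma_ra, double sigma_rb,
                  int radius, int passes) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int w = 2 * radius + 1;

  // spatial kernel, precomputed over the window
  std::vector<double> ks((size_t)w * w * w);
  {
    const double inv2s2 = 1.0 / (2.0 * sigma_s * sigma_s);
    size_t k = 0;
    for (int dz = -radius; dz <= radius; ++dz)
      for (int dy = -radius; dy <= radius; ++dy)
        for (int dx = -radius; dx <= radius; ++dx, ++k)
          ks[k] = std::exp(-(double)(dx * dx + dy * dy + dz * dz) * inv2s2);
  }

  std::vector<double> ca(a.begin(), a.end()), cb(b.begin(), b.end());
  std::vector<double> oa(n), ob(n);
  const double inv2ra2 = 1.0 / (2.0 * sigma_ra * sigma_ra);
  const double inv2rb2 = 1.0 / (2.0 * sigma_rb * sigma_rb);

  for (int pass = 0; pass < passes; ++pass) {
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          const R_xlen_t c = (R_xlen_t)x + nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
          const double va = ca[c], vb = cb[c];
          double sw = 0.0, sa = 0.0, sb = 0.0;
          size_t k = 0;
          for (int dz = -radius; dz <= radius; ++dz) {
            const int zz = mirror(z + dz, nz);
            for (int dy = -radius; dy <= radius; ++dy) {
              const int yy = mirror(y + dy, ny);
              const R_xlen_t base = nx * ((R_xlen_t)yy + (R_xlen_t)ny * zz);
              for (int dx = -radius; dx <= radius; ++dx, ++k) {
                const int xx = mirror(x + dx, nx);
                const R_xlen_t q = (R_xlen_t)xx + base;
                const double da = ca[q] - va, db = cb[q] - vb;
                const double wgt = ks[k] *
                  std::exp(-(da * da * inv2ra2 + db * db * inv2rb2));
                sw += wgt;
                sa += wgt * ca[q];
                sb += wgt * cb[q];
              }
            }
          }
          oa[c] = sa / sw;
          ob[c] = sb / sw;
        }
      }
    }
    ca = oa;
    cb = ob;
  }

  NumericVector ra(oa.begin(), oa.end()), rb(ob.begin(), ob.end());
  ra.attr("dim") = dim;
  rb.attr("dim") = dim;
  return List::create(_["a"] = ra, _["b"] = rb);
}
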