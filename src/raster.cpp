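#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Voxel-center point-in-tube test against a densely sampled curve: voxel is
// foreground iff some curve sample c_i has |x - c_i| <= r_i. Sampling must be
// much finer than the voxel size (the caller uses min(spacing)/4) so the
// sample-union is indistinguishable from the continuous tube.
// [[Rcpp::export(name = ".rasterize_tube")]]
LogicalVector rasterize_tube(NumericMatrix pts, NumericVector radii,
                             IntegerVector dim, NumericVector spacing,
                             NumericVector origin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector mask((R_xlen_t)nx * ny * nz, false);
  for (int i = 0; i < pts.nrow(); ++i) {
    double cx = pts(i, 0), cy = pts(i, 1), cz = pts(i, 2), r = radii[i];
    double r2 = r * r;
    int x0 = (int)std::ceil((cx - r - origin[0]) / spacing[0]);
    int x1 = (int)std::floor((cx + r - origin[0]) / spacing[0]);
    int y0 = (int)std::ceil((cy - r - origin[1]) / spacing[1]);
    int y1 = (int)std::floor((cy + r - origin[1]) / spacing[1]);
    int z0 = (int)std::ceil((cz - r - origin[2]) / spacing[2]);
    int z1 = (int)std::floor((cz + r - origin[2]) / spacing[2]);
    if (x0 < 0) x0 = 0; if (y0 < 0) y0 = 0; if (z0 < 0) z0 = 0;
    if (x1 >= nx) x1 = nx - 1; if (y1 >= ny) y1 = ny - 1; if (z1 >= nz) z1 = nz - 1;
    for (int z = z0; z <= z1; ++z) {
      double dz = origin[2] + z * spacing[2] - cz;
      for (int y = y0; y <= y1; ++y) {
        double dy = origin[1] + y * spacing[1] - cy;
        double dyz = dy * dy + dz * dz;
        if (dyz > r2) continue;
        R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
        for (int x = x0; x <= x1; ++x) {
          double dx = origin[0] + x * spacing[0] - cx;
          if (dx * dx + dyz <= r2) mask[base + x] = true;
        }
      }
    }
  }
  return mask;
}
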