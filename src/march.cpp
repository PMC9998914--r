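#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Boundary-distance extraction: march from each center along each direction
// in increments of `step` until the sampled voxel (nearest-voxel lookup)
// leaves the mask, then bisect the bracket 5 times (bracket width step/32).
// centers: k x 3 (0-based, inside the mask); dirs: n x 3 unit vectors.
// Returns k x n distances.
// [[Rcpp::export]]
NumericMatrix boundary_march_cpp(LogicalVector mask, IntegerVector dim,
                                 NumericMatrix centers, NumericMatrix dirs,
                                 double step) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int k = centers.nrow(), n = dirs.nrow();
  const double tmax = std::sqrt((double)nz * nz + (double)ny * ny +
                                (double)nx * nx) + 2 * step;
  NumericMatrix out(k, n);
  auto inside = [&](double z, double y, double x) -> bool {
    int iz = (int)std::lround(z), iy = (int)std::lround(y),
        ix = (int)std::lround(x);
    if (iz < 0 || iz >= nz || iy < 0 || iy >= ny || ix < 0 || ix >= nx)
      return false;
    return mask[iz + (R_xlen_t)nz * (iy + (R_xlen_t)ny * ix)];
  };
  for (int i = 0; i < k; i++) {
    const double cz = centers(i, 0), cy = centers(i, 1), cx = centers(i, 2);
    for (int j = 0; j < n; j++) {
      const double dz = dirs(j, 0), dy = dirs(j, 1), dx = dirs(j, 2);
      double lo = 0, t = 0;
      while (true) {
        double t2 = t + step;
        if (t2 > tmax ||
            !inside(cz + dz * t2, cy + dy * t2, cx + dx * t2)) {
          lo = t;
          t = t2;
          break;
        }
        t = t2;
      }
      double hi = t;
      for (int b = 0; b < 5; b++) {
        double mid = (lo + hi) / 2;
        if (inside(cz + dz * mid, cy + dy * mid, cx + dx * mid)) lo = mid;
        else hi = mid;
      }
      out(i, j) = (lo + hi) / 2;
    }
  }
  return out;
}
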