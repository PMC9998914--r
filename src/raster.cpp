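#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rasterize a star-convex polyhedron given by per-ray boundary distances.
// The radius function r(u) interpolates the per-ray distances barycentrically
// over the spherical triangulation of the ray directions: for a voxel offset
// u from the center, coefficients c = Minv %*% u (Minv the inverse of the
// 3x3 matrix whose columns are the triangle's unit directions) are all >= 0
// exactly when u falls in that triangle's cone; the normalised coefficients
// b = c / sum(c) are the barycentric weights and r = b . (d1, d2, d3).
// A voxel is inside iff |u| <= r(u/|u|).
//
// minv:  F x 9 matrix, row j = column-major inverse for facet j.
// fdist: F x 3 matrix, per-facet vertex distances.
// origin/bdim: 0-based corner and size of the bounding box scanned.
// center: absolute (z, y, x), 0-based. rmax: radius bound for early reject.
// [[Rcpp::export]]
LogicalVector rasterize_star_cpp(NumericVector center, NumericMatrix minv,
                                 NumericMatrix fdist, IntegerVector origin,
                                 IntegerVector bdim, double rmax) {
  const int nz = bdim[0], ny = bdim[1], nx = bdim[2];
  const int F = minv.nrow();
  const double eps = 1e-9;
  LogicalVector out((R_xlen_t)nz * ny * nx);
  const double r2max = (rmax + 1e-9) * (rmax + 1e-9);
  R_xlen_t idx = 0;
  for (int x = 0; x < nx; x++)
    for (int y = 0; y < ny; y++)
      for (int z = 0; z < nz; z++, idx++) {
        double u0 = origin[0] + z - center[0];
        double u1 = origin[1] + y - center[1];
        double u2 = origin[2] + x - center[2];
        double r2 = u0 * u0 + u1 * u1 + u2 * u2;
        if (r2 > r2max) { out[idx] = false; continue; }
        if (r2 < 1e-12) { out[idx] = true; continue; }  // center voxel
        int best_j = -1;
        double best_mn = -R_PosInf;
        double c1 = 0, c2 = 0, c3 = 0;
        for (int j = 0; j < F; j++) {
          const double a1 = minv(j, 0) * u0 + minv(j, 3) * u1 + minv(j, 6) * u2;
          const double a2 = minv(j, 1) * u0 + minv(j, 4) * u1 + minv(j, 7) * u2;
          const double a3 = minv(j, 2) * u0 + minv(j, 5) * u1 + minv(j, 8) * u2;
          double mn = std::min(a1, std::min(a2, a3));
          if (mn >= -eps) { best_j = j; c1 = a1; c2 = a2; c3 = a3; break; }
          if (mn > best_mn) { best_mn = mn; best_j = j; c1 = a1; c2 = a2; c3 = a3; }
        }
        double s = c1 + c2 + c3;
        if (s <= 0) { out[idx] = false; continue; }  // numerically degenerate
        double r = (c1 * fdist(best_j, 0) + c2 * fdist(best_j, 1) +
                    c3 * fdist(best_j, 2)) / s;
        out[idx] = std::sqrt(r2) <= r + 1e-9;
      }
  return out;
}
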