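#include <Rcpp.h>
#include <vector>
#include <set>
#include <cmath>
using namespace Rcpp;

namespace {

struct Face {
  int a, b, c;
  double nx, ny, nz, off;  // outward normal, n . x <= off inside
  bool alive;
};

inline void face_plane(const NumericMatrix& P, Face& f) {
  double ux = P(f.b, 0) - P(f.a, 0), uy = P(f.b, 1) - P(f.a, 1),
         uz = P(f.b, 2) - P(f.a, 2);
  double vx = P(f.c, 0) - P(f.a, 0), vy = P(f.c, 1) - P(f.a, 1),
         vz = P(f.c, 2) - P(f.a, 2);
  f.nx = uy * vz - uz * vy;
  f.ny = uz * vx - ux * vz;
  f.nz = ux * vy - uy * vx;
  f.off = f.nx * P(f.a, 0) + f.ny * P(f.a, 1) + f.nz * P(f.a, 2);
}

inline double face_dist(const Face& f, double x, double y, double z) {
  return f.nx * x + f.ny * y + f.nz * z - f.off;
}

}  // namespace

// Incremental 3D convex hull. Points are rows (z, y, x) or any fixed axis
// order; the hull is axis-order agnostic. Returns triangular facets (1-based
// vertex indices into the input), unit outward normals and plane offsets so
// that a point p is inside iff normal . p <= offset for every facet.
// Degenerate inputs (< 4 points, or all coplanar within tolerance) return an
// empty facet list; callers fall back to a volume-based convention.
// [[Rcpp::export]]
List convex_hull3_cpp(NumericMatrix P) {
  const int n = P.nrow();
  List empty = List::create(_["facets"] = IntegerMatrix(0, 3),
                            _["normals"] = NumericMatrix(0, 3),
                            _["offsets"] = NumericVector(0));
  if (n < 4) return empty;

  double scale = 0;
  for (int i = 0; i < n; i++)
    for (int j = 0; j < 3; j++) scale = std::max(scale, std::fabs(P(i, j)));
  if (scale == 0) scale = 1;
  const double tol = 1e-9 * scale * scale;  // plane tests scale with area

  // initial simplex: extreme pair, then farthest from line, then from plane
  int i0 = 0, i1 = 0;
  double best = -1;
  for (int d = 0; d < 3; d++) {
    int lo = 0, hi = 0;
    for (int i = 1; i < n; i++) {
      if (P(i, d) < P(lo, d)) lo = i;
      if (P(i, d) > P(hi, d)) hi = i;
    }
    double dd = 0;
    for (int j = 0; j < 3; j++) {
      double t = P(hi, j) - P(lo, j);
      dd += t * t;
    }
    if (dd > best) { best = dd; i0 = lo; i1 = hi; }
  }
  if (best <= 0) return empty;

  int i2 = -1;
  best = tol;
  double ax = P(i1, 0) - P(i0, 0), ay = P(i1, 1) - P(i0, 1),
         az = P(i1, 2) - P(i0, 2);
  for (int i = 0; i < n; i++) {
    double bx = P(i, 0) - P(i0, 0), by = P(i, 1) - P(i0, 1),
           bz = P(i, 2) - P(i0, 2);
    double cx = ay * bz - az * by, cy = az * bx - ax * bz,
           cz = ax * by - ay * bx;
    double d = cx * cx + cy * cy + cz * cz;
    if (d > best) { best = d; i2 = i; }
  }
  if (i2 < 0) return empty;

  Face f0 = {i0, i1, i2, 0, 0, 0, 0, true};
  face_plane(P, f0);
  int i3 = -1;
  best = tol;
  for (int i = 0; i < n; i++) {
    double d = std::fabs(face_dist(f0, P(i, 0), P(i, 1), P(i, 2)));
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0) return empty;

  double cx = (P(i0, 0) + P(i1, 0) + P(i2, 0) + P(i3, 0)) / 4.0;
  double cy = (P(i0, 1) + P(i1, 1) + P(i2, 1) + P(i3, 1)) / 4.0;
  double cz = (P(i0, 2) + P(i1, 2) + P(i2, 2) + P(i3, 2)) / 4.0;

  std::vector<Face> faces;
  int tet[4][3] = {{i0, i1, i2}, {i0, i1, i3}, {i0, i2, i3}, {i1, i2, i3}};
  for (auto& t : tet) {
    Face f = {t[0], t[1], t[2], 0, 0, 0, 0, true};
    face_plane(P, f);
    if (face_dist(f, cx, cy, cz) > 0) { std::swap(f.b, f.c); face_plane(P, f); }
    faces.push_back(f);
  }

  for (int i = 0; i < n; i++) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    double px = P(i, 0), py = P(i, 1), pz = P(i, 2);
    std::vector<int> vis;
    for (size_t j = 0; j < faces.size(); j++)
      if (faces[j].alive && face_dist(faces[j], px, py, pz) > tol)
        vis.push_back((int)j);
    if (vis.empty()) continue;
    // horizon = directed edges of visible faces whose reverse is not visible
    std::set<std::pair<int, int> > edges;
    for (int j : vis) {
      const Face& f = faces[j];
      edges.insert({f.a, f.b});
      edges.insert({f.b, f.c});
      edges.insert({f.c, f.a});
    }
    for (int j : vis) faces[j].alive = false;
    for (const auto& e : edges) {
      if (edges.count({e.second, e.first})) continue;  // interior to the patch
      Face f = {e.first, e.second, i, 0, 0, 0, 0, true};
      face_plane(P, f);
      if (face_dist(f, cx, cy, cz) > 0) { std::swap(f.b, f.c); face_plane(P, f); }
      faces.push_back(f);
    }
  }

  int m = 0;
  for (auto& f : faces) if (f.alive) m++;
  IntegerMatrix facets(m, 3);
  NumericMatrix normals(m, 3);
  NumericVector offsets(m);
  int k = 0;
  for (auto& f : faces) {
    if (!f.alive) continue;
    double len = std::sqrt(f.nx * f.nx + f.ny * f.ny + f.nz * f.nz);
    if (len == 0) len = 1;
    facets(k, 0) = f.a + 1;
    facets(k, 1) = f.b + 1;
    facets(k, 2) = f.c + 1;
    normals(k, 0) = f.nx / len;
    normals(k, 1) = f.ny / len;
    normals(k, 2) = f.nz / len;
    offsets[k] = f.off / len;
    k++;
  }
  return List::create(_["facets"] = facets, _["normals"] = normals,
                      _["offsets"] = offsets);
}

// Flags grid voxels (0-based integer coordinates origin + index) lying inside
// the intersection of half-spaces normal . p <= offset + tol.
// [[Rcpp::export]]
LogicalVector in_hull_grid_cpp(IntegerVector origin, IntegerVector bdim,
                               NumericMatrix normals, NumericVector offsets,
                               double tol) {
  const int nz = bdim[0], ny = bdim[1], nx = bdim[2];
  const int m = normals.nrow();
  LogicalVector out((R_xlen_t)nz * ny * nx);
  R_xlen_t idx = 0;
  for (int x = 0; x < nx; x++)
    for (int y = 0; y < ny; y++)
      for (int z = 0; z < nz; z++, idx++) {
        double pz = origin[0] + z, py = origin[1] + y, px = origin[2] + x;
        bool in = true;
        for (int j = 0; j < m; j++) {
          if (normals(j, 0) * pz + normals(j, 1) * py + normals(j, 2) * px >
              offsets[j] + tol) {
            in = false;
            break;
          }
        }
        out[idx] = in;
      }
  return out;
}
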