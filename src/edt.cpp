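#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// 1D squared distance transform (Felzenszwalb & Huttenlocher), lower envelope
// of parabolas rooted at f. d, v, z are scratch buffers of length >= n (+1 for z).
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -R_PosInf;
  z[1] = R_PosInf;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = R_PosInf;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Exact squared Euclidean distance to the nearest background (FALSE) voxel.
// Layout: linear index = z + nz*(y + ny*x), i.e. first dimension fastest.
// [[Rcpp::export]]
NumericVector edt_squared_cpp(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  const double INF = 1e30;
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // along z
  for (int x = 0; x < nx; x++)
    for (int y = 0; y < ny; y++) {
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int q = 0; q < nz; q++) f[q] = out[base + q];
      dt1d(f, d, v, z, nz);
      for (int q = 0; q < nz; q++) out[base + q] = d[q];
    }
  // along y
  for (int x = 0; x < nx; x++)
    for (int zz = 0; zz < nz; zz++) {
      R_xlen_t base = zz + (R_xlen_t)nz * ny * x;
      for (int q = 0; q < ny; q++) f[q] = out[base + (R_xlen_t)nz * q];
      dt1d(f, d, v, z, ny);
      for (int q = 0; q < ny; q++) out[base + (R_xlen_t)nz * q] = d[q];
    }
  // along x
  R_xlen_t sx = (R_xlen_t)nz * ny;
  for (int y = 0; y < ny; y++)
    for (int zz = 0; zz < nz; zz++) {
      R_xlen_t base = zz + (R_xlen_t)nz * y;
      for (int q = 0; q < nx; q++) f[q] = out[base + sx * q];
      dt1d(f, d, v, z, nx);
      for (int q = 0; q < nx; q++) out[base + sx * q] = d[q];
    }
  return out;
}

// Local maxima of val (26-connectivity), restricted to val > 0. Plateaus
// (connected runs of equal value none of whose members has a greater
// neighbour) are merged to a single representative: the plateau voxel closest
// to the plateau centroid, ties broken by lexicographic (z, y, x) order.
// Returns a k x 3 matrix of 0-based (z, y, x) coordinates plus values.
// [[Rcpp::export]]
List local_maxima_cpp(NumericVector val, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<char> cand(n, 0);

  for (int x = 0; x < nx; x++)
    for (int y = 0; y < ny; y++)
      for (int z = 0; z < nz; z++) {
        R_xlen_t i = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        double v0 = val[i];
        if (v0 <= 0) continue;
        bool ok = true;
        for (int dx = -1; dx <= 1 && ok; dx++)
          for (int dy = -1; dy <= 1 && ok; dy++)
            for (int dz = -1; dz <= 1 && ok; dz++) {
              if (!dx && !dy && !dz) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                continue;
              if (val[z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2)] > v0)
                ok = false;
            }
        if (ok) cand[i] = 1;
      }

  // flood plateaus of equal-valued candidate voxels
  std::vector<int> reps_z, reps_y, reps_x;
  std::vector<double> reps_v;
  std::vector<char> seen(n, 0);
  std::vector<R_xlen_t> comp;
  for (R_xlen_t i0 = 0; i0 < n; i0++) {
    if (!cand[i0] || seen[i0]) continue;
    comp.clear();
    std::queue<R_xlen_t> q;
    q.push(i0);
    seen[i0] = 1;
    double v0 = val[i0];
    while (!q.empty()) {
      R_xlen_t i = q.front();
      q.pop();
      comp.push_back(i);
      int z = (int)(i % nz);
      int y = (int)((i / nz) % ny);
      int x = (int)(i / ((R_xlen_t)nz * ny));
      for (int dx = -1; dx <= 1; dx++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dz = -1; dz <= 1; dz++) {
            if (!dx && !dy && !dz) continue;
            int x2 = x + dx, y2 = y + dy, z2 = z + dz;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
              continue;
            R_xlen_t j = z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
            if (cand[j] && !seen[j] && val[j] == v0) {
              seen[j] = 1;
              q.push(j);
            }
          }
    }
    double cz = 0, cy = 0, cx = 0;
    for (R_xlen_t i : comp) {
      cz += (double)(i % nz);
      cy += (double)((i / nz) % ny);
      cx += (double)(i / ((R_xlen_t)nz * ny));
    }
    cz /= comp.size(); cy /= comp.size(); cx /= comp.size();
    double best = R_PosInf;
    int bz = 0, by = 0, bx = 0;
    for (R_xlen_t i : comp) {
      int z = (int)(i % nz);
      int y = (int)((i / nz) % ny);
      int x = (int)(i / ((R_xlen_t)nz * ny));
      double d = (z - cz) * (z - cz) + (y - cy) * (y - cy) + (x - cx) * (x - cx);
      bool better = d < best - 1e-12;
      if (!better && d < best + 1e-12) {
        // tie: lexicographic (z, y, x)
        if (z < bz || (z == bz && (y < by || (y == by && x < bx)))) better = true;
      }
      if (better) { best = d; bz = z; by = y; bx = x; }
    }
    reps_z.push_back(bz); reps_y.push_back(by); reps_x.push_back(bx);
    reps_v.push_back(v0);
  }

  int k = (int)reps_z.size();
  IntegerMatrix centers(k, 3);
  NumericVector values(k);
  for (int i = 0; i < k; i++) {
    centers(i, 0) = reps_z[i];
    centers(i, 1) = reps_y[i];
    centers(i, 2) = reps_x[i];
    values[i] = reps_v[i];
  }
  return List::create(_["centers"] = centers, _["values"] = values);
}
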