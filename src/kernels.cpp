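#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Deterministic sub-voxel offsets applied to every query point so that voxel
// centers never land exactly on mesh edges/vertices or axis-aligned facet
// planes (simulation-of-simplicity style tie-break). Relative to spacing, so
// the volume perturbation is O(1e-4 * spacing) and identical for both meshes
// of an intersection query (the common grid keeps the kernel symmetric).
static const double JIT_X = 7.548776662466927e-5;
static const double JIT_Y = 5.698402909980532e-5;
static const double JIT_Z = 3.819660112501051e-5;

// Column parity ray-cast voxelizer. Casts one +z ray per (x, y) voxel column,
// accumulates triangle crossings, and marks voxel centers lying inside an odd
// number of surface crossings. Watertight input is assumed (checked in R).
// [[Rcpp::export]]
LogicalVector cpp_voxelize(const NumericMatrix& V, const IntegerMatrix& F,
                           const NumericVector& origin, const double spacing,
                           const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ncol = nx * ny;
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double ex = JIT_X * spacing, ey = JIT_Y * spacing, ez = JIT_Z * spacing;

  std::vector< std::vector<double> > crossings(ncol);

  const int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    const int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    const double ax = V(a, 0), ay = V(a, 1), az = V(a, 2);
    const double bx = V(b, 0), by = V(b, 1), bz = V(b, 2);
    const double cx = V(c, 0), cy = V(c, 1), cz = V(c, 2);

    // 2D signed area in xy; triangles parallel to z never cross a +z ray
    const double det = (bx - ax) * (cy - ay) - (cx - ax) * (by - ay);
    if (det == 0.0) continue;

    const double xmin = std::min(ax, std::min(bx, cx));
    const double xmax = std::max(ax, std::max(bx, cx));
    const double ymin = std::min(ay, std::min(by, cy));
    const double ymax = std::max(ay, std::max(by, cy));

    // voxel-column centers covered by the triangle's xy bounding box
    int i0 = (int)std::floor((xmin - ox - ex) / spacing - 0.5);
    int i1 = (int)std::ceil((xmax - ox - ex) / spacing - 0.5);
    int j0 = (int)std::floor((ymin - oy - ey) / spacing - 0.5);
    int j1 = (int)std::ceil((ymax - oy - ey) / spacing - 0.5);
    i0 = std::max(i0, 0); j0 = std::max(j0, 0);
    i1 = std::min(i1, nx - 1); j1 = std::min(j1, ny - 1);

    for (int j = j0; j <= j1; ++j) {
      const double py = oy + (j + 0.5) * spacing + ey;
      for (int i = i0; i <= i1; ++i) {
        const double px = ox + (i + 0.5) * spacing + ex;
        // barycentric test in the xy projection
        const double w0 = ((bx - px) * (cy - py) - (cx - px) * (by - py)) / det;
        const double w1 = ((cx - px) * (ay - py) - (ax - px) * (cy - py)) / det;
        const double w2 = 1.0 - w0 - w1;
        if (w0 < 0.0 || w1 < 0.0 || w2 < 0.0) continue;
        const double zhit = w0 * az + w1 * bz + w2 * cz;
        crossings[i + nx * j].push_back(zhit);
      }
    }
  }

  LogicalVector occ(nx * ny * nz, false);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      std::vector<double>& cr = crossings[i + nx * j];
      if (cr.empty()) continue;
      std::sort(cr.begin(), cr.end());
      // voxel center is inside iff an odd number of crossings lie below it
      size_t idx = 0;
      int parity = 0;
      for (int k = 0; k < nz; ++k) {
        const double pz = oz + (k + 0.5) * spacing + ez;
        while (idx < cr.size() && cr[idx] < pz) { parity ^= 1; ++idx; }
        if (parity) occ[i + nx * (j + (R_xlen_t)ny * k)] = true;
      }
    }
  }
  return occ;
}

// Generalized winding number of each query point with respect to the surface
// (van Oosterom & Strackee solid-angle formula summed over triangles, divided
// by 4*pi). ~1 inside a watertight outward-oriented surface, ~0 outside.
// [[Rcpp::export]]
NumericVector cpp_winding_number(const NumericMatrix& V, const IntegerMatrix& F,
                                 const NumericMatrix& P) {
  const int np = P.nrow(), nf = F.nrow();
  NumericVector w(np);
  for (int p = 0; p < np; ++p) {
    const double px = P(p, 0), py = P(p, 1), pz = P(p, 2);
    double total = 0.0;
    for (int f = 0; f < nf; ++f) {
      const int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
      const double ax = V(ia, 0) - px, ay = V(ia, 1) - py, az = V(ia, 2) - pz;
      const double bx = V(ib, 0) - px, by = V(ib, 1) - py, bz = V(ib, 2) - pz;
      const double cx = V(ic, 0) - px, cy = V(ic, 1) - py, cz = V(ic, 2) - pz;
      const double la = std::sqrt(ax * ax + ay * ay + az * az);
      const double lb = std::sqrt(bx * bx + by * by + bz * bz);
      const double lc = std::sqrt(cx * cx + cy * cy + cz * cz);
      const double num = ax * (by * cz - bz * cy)
                       - ay * (bx * cz - bz * cx)
                       + az * (bx * cy - by * cx);
      const double den = la * lb * lc + (ax * bx + ay * by + az * bz) * lc
                       + (bx * cx + by * cy + bz * cz) * la
                       + (ax * cx + ay * cy + az * cz) * lb;
      total += 2.0 * std::atan2(num, den);
    }
    w[p] = total / (4.0 * M_PI);
  }
  return w;
}

// All ray-triangle intersection parameters t (Moller-Trumbore) for a single
// ray; both signs of t are returned, the caller picks the hit it wants.
// [[Rcpp::export]]
List cpp_ray_hits(const NumericMatrix& V, const IntegerMatrix& F,
                  const NumericVector& orig, const NumericVector& dir) {
  const double eps = 1e-12;
  std::vector<double> ts;
  std::vector<int> tri;
  const int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    const int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
    const double e1x = V(ib, 0) - V(ia, 0), e1y = V(ib, 1) - V(ia, 1), e1z = V(ib, 2) - V(ia, 2);
    const double e2x = V(ic, 0) - V(ia, 0), e2y = V(ic, 1) - V(ia, 1), e2z = V(ic, 2) - V(ia, 2);
    const double hx = dir[1] * e2z - dir[2] * e2y;
    const double hy = dir[2] * e2x - dir[0] * e2z;
    const double hz = dir[0] * e2y - dir[1] * e2x;
    const double a = e1x * hx + e1y * hy + e1z * hz;
    if (std::fabs(a) < eps) continue;
    const double inv = 1.0 / a;
    const double sx = orig[0] - V(ia, 0), sy = orig[1] - V(ia, 1), sz = orig[2] - V(ia, 2);
    const double u = inv * (sx * hx + sy * hy + sz * hz);
    if (u < -1e-9 || u > 1.0 + 1e-9) continue;
    const double qx = sy * e1z - sz * e1y;
    const double qy = sz * e1x - sx * e1z;
    const double qz = sx * e1y - sy * e1x;
    const double v = inv * (dir[0] * qx + dir[1] * qy + dir[2] * qz);
    if (v < -1e-9 || u + v > 1.0 + 1e-9) continue;
    const double t = inv * (e2x * qx + e2y * qy + e2z * qz);
    ts.push_back(t);
    tri.push_back(f + 1);
  }
  return List::create(_["t"] = wrap(ts), _["face"] = wrap(tri));
}
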