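// Lattice-based tetrahedral meshing of implicit domains.
//
// The domain is described either by a union of analytic primitives
// (spheres / cylinders, combined by min of signed distances) or by the
// signed distance to a watertight triangulated surface.  A Freudenthal
// (6-tets-per-cube) lattice covers the bounding box; lattice vertices
// closer to the zero level set than warp_frac * spacing are projected
// onto it (isosurface stuffing), then lattice tets crossing the surface
// are clipped with cut points obtained by bisection along edges.
// Cut-cell prisms are split with the global-vertex-order rule of
// Dompierre et al., which keeps faces conforming between neighbours.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <functional>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
  Vec3(double a = 0, double b = 0, double c = 0) : x(a), y(b), z(c) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm() const { return std::sqrt(dot(*this)); }
};

// ---- analytic primitives ---------------------------------------------------
// row layout: type, p1..p8
//   type 1 sphere:            cx cy cz r
//   type 2 infinite cylinder: ax ay az dx dy dz r      (d unit)
//   type 3 capped cylinder:   ax ay az dx dy dz r hl   (a = midpoint, hl half-length)
double prim_phi(const NumericMatrix& P, const Vec3& q) {
  double best = 1e300;
  for (int i = 0; i < P.nrow(); ++i) {
    int type = (int)P(i, 0);
    double d;
    if (type == 1) {
      Vec3 c(P(i, 1), P(i, 2), P(i, 3));
      d = (q - c).norm() - P(i, 4);
    } else {
      Vec3 a(P(i, 1), P(i, 2), P(i, 3));
      Vec3 dir(P(i, 4), P(i, 5), P(i, 6));
      Vec3 w = q - a;
      double t = w.dot(dir);
      double rad = (w - dir * t).norm() - P(i, 7);
      if (type == 2) {
        d = rad;
      } else {
        double ax = std::fabs(t) - P(i, 8);
        // exact SDF of a finite capped cylinder
        double ro = std::max(rad, 0.0), ao = std::max(ax, 0.0);
        d = std::min(std::max(rad, ax), 0.0) + std::sqrt(ro * ro + ao * ao);
      }
    }
    if (d < best) best = d;
  }
  return best;
}

// ---- signed distance to a triangulated surface -----------------------------
struct MeshSDF {
  const NumericMatrix& V;
  const IntegerMatrix& F;  // 0-based
  double cell;
  Vec3 lo;
  int nx, ny, nz;
  std::vector<std::vector<int>> bins;

  MeshSDF(const NumericMatrix& V_, const IntegerMatrix& F_) : V(V_), F(F_) {
    Vec3 hi(-1e300, -1e300, -1e300);
    lo = Vec3(1e300, 1e300, 1e300);
    for (int i = 0; i < V.nrow(); ++i) {
      lo.x = std::min(lo.x, V(i, 0)); hi.x = std::max(hi.x, V(i, 0));
      lo.y = std::min(lo.y, V(i, 1)); hi.y = std::max(hi.y, V(i, 1));
      lo.z = std::min(lo.z, V(i, 2)); hi.z = std::max(hi.z, V(i, 2));
    }
    Vec3 ext = hi - lo;
    double vol = std::max(ext.x * ext.y * ext.z, 1e-30);
    cell = std::cbrt(vol / std::max(1, F.nrow())) * 2.0;
    nx = std::max(1, (int)(ext.x / cell) + 1);
    ny = std::max(1, (int)(ext.y / cell) + 1);
    nz = std::max(1, (int)(ext.z / cell) + 1);
    bins.resize((size_t)nx * ny * nz);
    for (int f = 0; f < F.nrow(); ++f) {
      double bx0 = 1e300, bx1 = -1e300, by0 = 1e300, by1 = -1e300, bz0 = 1e300, bz1 = -1e300;
      for (int k = 0; k < 3; ++k) {
        int v = F(f, k);
        bx0 = std::min(bx0, V(v, 0)); bx1 = std::max(bx1, V(v, 0));
        by0 = std::min(by0, V(v, 1)); by1 = std::max(by1, V(v, 1));
        bz0 = std::min(bz0, V(v, 2)); bz1 = std::max(bz1, V(v, 2));
      }
      int i0 = idx(bx0, lo.x), i1 = idx(bx1, lo.x), j0 = idx(by0, lo.y), j1 = idx(by1, lo.y),
          k0 = idx(bz0, lo.z), k1 = idx(bz1, lo.z);
      for (int i = std::max(0, i0); i <= std::min(nx - 1, i1); ++i)
        for (int j = std::max(0, j0); j <= std::min(ny - 1, j1); ++j)
          for (int k = std::max(0, k0); k <= std::min(nz - 1, k1); ++k)
            bins[bin(i, j, k)].push_back(f);
    }
  }
  int idx(double v, double l) const { return (int)std::floor((v - l) / cell); }
  size_t bin(int i, int j, int k) const { return ((size_t)i * ny + j) * nz + k; }

  Vec3 vert(int v) const { return Vec3(V(v, 0), V(v, 1), V(v, 2)); }

  static double dist2_point_tri(const Vec3& p, const Vec3& a, const Vec3& b, const Vec3& c) {
    // Ericson, Real-Time Collision Detection
    Vec3 ab = b - a, ac = c - a, ap = p - a;
    double d1 = ab.dot(ap), d2 = ac.dot(ap);
    if (d1 <= 0 && d2 <= 0) return ap.dot(ap);
    Vec3 bp = p - b;
    double d3 = ab.dot(bp), d4 = ac.dot(bp);
    if (d3 >= 0 && d4 <= d3) return bp.dot(bp);
    double vc = d1 * d4 - d3 * d2;
    if (vc <= 0 && d1 >= 0 && d3 <= 0) {
      double v = d1 / (d1 - d3);
      Vec3 q = a + ab * v - p;
      return q.dot(q);
    }
    Vec3 cp = p - c;
    double d5 = ab.dot(cp), d6 = ac.dot(cp);
    if (d6 >= 0 && d5 <= d6) return cp.dot(cp);
    double vb = d5 * d2 - d1 * d6;
    if (vb <= 0 && d2 >= 0 && d6 <= 0) {
      double w = d2 / (d2 - d6);
      Vec3 q = a + ac * w - p;
      return q.dot(q);
    }
    double va = d3 * d6 - d5 * d4;
    if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
      double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
      Vec3 q = b + (c - b) * w - p;
      return q.dot(q);
    }
    double denom = 1.0 / (va + vb + vc);
    double v = vb * denom, w = vc * denom;
    Vec3 q = a + ab * v + ac * w - p;
    return q.dot(q);
  }

  double unsigned_dist(const Vec3& p, int* nearest = nullptr) const {
    int pi = std::min(nx - 1, std::max(0, idx(p.x, lo.x)));
    int pj = std::min(ny - 1, std::max(0, idx(p.y, lo.y)));
    int pk = std::min(nz - 1, std::max(0, idx(p.z, lo.z)));
    double best = 1e300;
    int bestf = -1;
    int maxr = std::max(nx, std::max(ny, nz));
    for (int r = 0; r <= maxr; ++r) {
      if (bestf >= 0 && (double)(r - 1) * cell > std::sqrt(best)) break;
      for (int i = std::max(0, pi - r); i <= std::min(nx - 1, pi + r); ++i)
        for (int j = std::max(0, pj - r); j <= std::min(ny - 1, pj + r); ++j)
          for (int k = std::max(0, pk - r); k <= std::min(nz - 1, pk + r); ++k) {
            if (std::max(std::abs(i - pi), std::max(std::abs(j - pj), std::abs(k - pk))) != r)
              continue;
            for (int f : bins[bin(i, j, k)]) {
              double d2 = dist2_point_tri(p, vert(F(f, 0)), vert(F(f, 1)), vert(F(f, 2)));
              if (d2 < best) { best = d2; bestf = f; }
            }
          }
    }
    if (nearest) *nearest = bestf;
    return std::sqrt(best);
  }

  mutable std::vector<int> stamp;
  mutable int stampval = 0;

  // parity ray cast along +z (tiny fixed skew to dodge shared edges),
  // visiting only the triangles binned in the ray's grid column
  bool inside(const Vec3& p) const {
    if (stamp.empty()) stamp.assign(F.nrow(), -1);
    ++stampval;
    Vec3 dir(1e-6, 2e-6, 1.0);
    int ci = std::min(nx - 1, std::max(0, idx(p.x, lo.x)));
    int cj = std::min(ny - 1, std::max(0, idx(p.y, lo.y)));
    int ck = std::max(0, idx(p.z, lo.z));
    int cnt = 0;
    for (int k = ck; k < nz; ++k) {
      for (int f : bins[bin(ci, cj, k)]) {
        if (stamp[f] == stampval) continue;
        stamp[f] = stampval;
        if (ray_hits(p, dir, f)) ++cnt;
      }
    }
    return (cnt % 2) == 1;
  }

  bool ray_hits(const Vec3& p, const Vec3& dir, int f) const {
    Vec3 a = vert(F(f, 0)), b = vert(F(f, 1)), c = vert(F(f, 2));
    // Moller-Trumbore
    Vec3 e1 = b - a, e2 = c - a;
    Vec3 pv = dir.cross(e2);
    double det = e1.dot(pv);
    if (std::fabs(det) < 1e-14) return false;
    double inv = 1.0 / det;
    Vec3 tv = p - a;
    double u = tv.dot(pv) * inv;
    if (u < 0 || u > 1) return false;
    Vec3 qv = tv.cross(e1);
    double v = dir.dot(qv) * inv;
    if (v < 0 || u + v > 1) return false;
    double t = e2.dot(qv) * inv;
    return t > 1e-12;
  }

  double phi(const Vec3& p) const {
    double d = unsigned_dist(p);
    return inside(p) ? -d : d;
  }
};

// ---- Freudenthal lattice clipping ------------------------------------------
struct Mesher {
  std::function<double(const Vec3&)> phi;
  Vec3 lo;
  double ax, ay, az;
  int nx, ny, nz;  // cells
  double warp_frac;

  std::vector<Vec3> pts;
  std::vector<double> phiv;
  std::vector<int> emitted;                     // tets, 4 ids each
  std::unordered_map<uint64_t, int> cutmap;     // edge -> cut vertex id

  int gid(int i, int j, int k) const {
    return (i * (ny + 1) + j) * (nz + 1) + k;
  }

  void build_grid() {
    pts.resize((size_t)(nx + 1) * (ny + 1) * (nz + 1));
    phiv.resize(pts.size());
    for (int i = 0; i <= nx; ++i)
      for (int j = 0; j <= ny; ++j)
        for (int k = 0; k <= nz; ++k) {
          Vec3 p(lo.x + i * ax, lo.y + j * ay, lo.z + k * az);
          int g = gid(i, j, k);
          pts[g] = p;
          phiv[g] = phi(p);
        }
    // warp near-surface vertices onto the zero level set
    double amin = std::min(ax, std::min(ay, az));
    double tol = warp_frac * amin, eps = 1e-4 * amin;
    for (int i = 0; i <= nx; ++i)
      for (int j = 0; j <= ny; ++j)
        for (int k = 0; k <= nz; ++k) {
          int g = gid(i, j, k);
          if (std::fabs(phiv[g]) >= tol) continue;
          Vec3 p = pts[g];
          for (int it = 0; it < 4; ++it) {
            double f0 = phi(p);
            if (std::fabs(f0) < 1e-12 * amin) break;
            Vec3 grad((phi(Vec3(p.x + eps, p.y, p.z)) - phi(Vec3(p.x - eps, p.y, p.z))) / (2 * eps),
                      (phi(Vec3(p.x, p.y + eps, p.z)) - phi(Vec3(p.x, p.y - eps, p.z))) / (2 * eps),
                      (phi(Vec3(p.x, p.y, p.z + eps)) - phi(Vec3(p.x, p.y, p.z - eps))) / (2 * eps));
            double g2 = grad.dot(grad);
            if (g2 < 1e-20) break;
            Vec3 step = grad * (f0 / g2);
            // vertices on box faces stay on them, keeping lattice-plane caps planar
            if (i == 0 || i == nx) step.x = 0;
            if (j == 0 || j == ny) step.y = 0;
            if (k == 0 || k == nz) step.z = 0;
            p = p - step;
          }
          // cap-plane-locked vertices may not reach the surface; only accept
          // the warp when it did (otherwise keep original point and value)
          double f1 = phi(p);
          if (std::fabs(f1) < 0.05 * amin) {
            pts[g] = p;
            phiv[g] = 0.0;
          }
        }
  }

  bool is_in(int g) const { return phiv[g] <= 0.0; }

  int cut(int a, int b) {
    if (phiv[a] == 0.0) return a;
    if (phiv[b] == 0.0) return b;
    uint64_t key = ((uint64_t)std::min(a, b) << 32) | (uint64_t)std::max(a, b);
    auto it = cutmap.find(key);
    if (it != cutmap.end()) return it->second;
    Vec3 pa = pts[a], pb = pts[b];
    double fa = phiv[a], fb = phiv[b];
    if (fa > 0) { std::swap(pa, pb); std::swap(fa, fb); }
    // bisection: fa < 0 < fb
    Vec3 mid;
    for (int it2 = 0; it2 < 20; ++it2) {
      mid = (pa + pb) * 0.5;
      double fm = phi(mid);
      if (fm <= 0) pa = mid; else pb = mid;
    }
    int id = (int)pts.size();
    pts.push_back((pa + pb) * 0.5);
    phiv.push_back(0.0);
    cutmap[key] = id;
    return id;
  }

  double vol6(int a, int b, int c, int d) const {
    Vec3 u = pts[b] - pts[a], v = pts[c] - pts[a], w = pts[d] - pts[a];
    return u.cross(v).dot(w);
  }

  void emit(int a, int b, int c, int d, double dropvol) {
    double v = vol6(a, b, c, d);
    if (std::fabs(v) <= dropvol) return;
    if (v < 0) std::swap(c, d);
    emitted.push_back(a); emitted.push_back(b);
    emitted.push_back(c); emitted.push_back(d);
  }

  // prism: bottom triangle (p0,p1,p2), top (p3,p4,p5), vertical edges i -> i+3
  void emit_prism(int pv[6], double dropvol) {
    // rotate / flip so the globally smallest vertex is local 0
    int mi = 0;
    for (int i = 1; i < 6; ++i)
      if (pv[i] < pv[mi]) mi = i;
    int w[6];
    if (mi >= 3) {  // flip top and bottom
      int t[6] = {pv[3], pv[4], pv[5], pv[0], pv[1], pv[2]};
      std::copy(t, t + 6, pv);
      mi -= 3;
    }
    int r = mi;  // rotate bottom triangle so mi -> 0
    for (int i = 0; i < 3; ++i) {
      w[i] = pv[(i + r) % 3];
      w[i + 3] = pv[3 + (i + r) % 3];
    }
    // remaining quad (1,2,5,4): diagonal through its smallest vertex
    bool diag15 = std::min(w[1], w[5]) < std::min(w[2], w[4]);
    if (diag15) {
      emit(w[0], w[1], w[2], w[5], dropvol);
      emit(w[0], w[1], w[5], w[4], dropvol);
      emit(w[0], w[4], w[5], w[3], dropvol);
    } else {
      emit(w[0], w[1], w[2], w[4], dropvol);
      emit(w[0], w[4], w[2], w[5], dropvol);
      emit(w[0], w[4], w[5], w[3], dropvol);
    }
  }

  void clip_tet(int v[4], double dropvol) {
    int in[4], out[4], ni = 0, no = 0;
    for (int i = 0; i < 4; ++i) {
      if (is_in(v[i])) in[ni++] = v[i]; else out[no++] = v[i];
    }
    if (ni == 0) return;
    if (ni == 4) { emit(v[0], v[1], v[2], v[3], dropvol); return; }
    if (ni == 1) {
      emit(in[0], cut(in[0], out[0]), cut(in[0], out[1]), cut(in[0], out[2]), dropvol);
    } else if (ni == 3) {
      int pv[6] = {in[0], in[1], in[2],
                   cut(in[0], out[0]), cut(in[1], out[0]), cut(in[2], out[0])};
      emit_prism(pv, dropvol);
    } else {  // ni == 2
      int pv[6] = {in[0], cut(in[0], out[0]), cut(in[0], out[1]),
                   in[1], cut(in[1], out[0]), cut(in[1], out[1])};
      emit_prism(pv, dropvol);
    }
  }

  void run() {
    build_grid();
    double dropvol = 1e-10 * ax * ay * az * 6.0;
    // Kuhn subdivision: 6 tets per cube, all sharing the main diagonal
    static const int kuhn[6][4] = {
        {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
        {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
    for (int i = 0; i < nx; ++i)
      for (int j = 0; j < ny; ++j)
        for (int k = 0; k < nz; ++k) {
          int c[8];
          for (int b = 0; b < 8; ++b)
            c[b] = gid(i + (b & 1), j + ((b >> 1) & 1), k + ((b >> 2) & 1));
          // quick reject: all 8 far outside
          bool any = false;
          for (int b = 0; b < 8; ++b)
            if (phiv[c[b]] <= 0) { any = true; break; }
          if (!any) continue;
          for (int t = 0; t < 6; ++t) {
            int v[4] = {c[kuhn[t][0]], c[kuhn[t][1]], c[kuhn[t][2]], c[kuhn[t][3]]};
            clip_tet(v, dropvol);
          }
        }
  }

  List finish() {
    int nt = (int)emitted.size() / 4;
    // compact vertex numbering
    std::vector<int> remap(pts.size(), -1);
    int nv = 0;
    for (int e : emitted)
      if (remap[e] < 0) remap[e] = nv++;
    NumericMatrix Vout(nv, 3);
    for (size_t i = 0; i < pts.size(); ++i)
      if (remap[i] >= 0) {
        Vout(remap[i], 0) = pts[i].x;
        Vout(remap[i], 1) = pts[i].y;
        Vout(remap[i], 2) = pts[i].z;
      }
    IntegerMatrix Tout(nt, 4);
    for (int t = 0; t < nt; ++t)
      for (int k = 0; k < 4; ++k)
        Tout(t, k) = remap[emitted[4 * t + k]] + 1;  // 1-based for R
    return List::create(_["vertices"] = Vout, _["tets"] = Tout);
  }
};

}  // namespace

// [[Rcpp::export]]
List lattice_mesh_primitives_cpp(NumericMatrix prims, NumericVector lower,
                                 NumericVector upper, NumericVector spacing,
                                 double warp_frac) {
  Mesher m;
  m.phi = [&prims](const Vec3& p) { return prim_phi(prims, p); };
  m.lo = Vec3(lower[0], lower[1], lower[2]);
  m.nx = std::max(1, (int)std::lround((upper[0] - lower[0]) / spacing[0]));
  m.ny = std::max(1, (int)std::lround((upper[1] - lower[1]) / spacing[1]));
  m.nz = std::max(1, (int)std::lround((upper[2] - lower[2]) / spacing[2]));
  m.ax = (upper[0] - lower[0]) / m.nx;
  m.ay = (upper[1] - lower[1]) / m.ny;
  m.az = (upper[2] - lower[2]) / m.nz;
  m.warp_frac = warp_frac;
  m.run();
  return m.finish();
}

// [[Rcpp::export]]
List lattice_mesh_surface_cpp(NumericMatrix V, IntegerMatrix F, NumericVector lower,
                              NumericVector upper, NumericVector spacing,
                              double warp_frac) {
  MeshSDF sdf(V, F);
  Mesher m;
  m.phi = [&sdf](const Vec3& p) { return sdf.phi(p); };
  m.lo = Vec3(lower[0], lower[1], lower[2]);
  m.nx = std::max(1, (int)std::lround((upper[0] - lower[0]) / spacing[0]));
  m.ny = std::max(1, (int)std::lround((upper[1] - lower[1]) / spacing[1]));
  m.nz = std::max(1, (int)std::lround((upper[2] - lower[2]) / spacing[2]));
  m.ax = (upper[0] - lower[0]) / m.nx;
  m.ay = (upper[1] - lower[1]) / m.ny;
  m.az = (upper[2] - lower[2]) / m.nz;
  m.warp_frac = warp_frac;
  m.run();
  return m.finish();
}

// [[Rcpp::export]]
NumericVector prim_phi_cpp(NumericMatrix prims, NumericMatrix Q) {
  NumericVector out(Q.nrow());
  for (int i = 0; i < Q.nrow(); ++i)
    out[i] = prim_phi(prims, Vec3(Q(i, 0), Q(i, 1), Q(i, 2)));
  return out;
}

// signed distance of query points to a watertight surface (negative inside)
// [[Rcpp::export]]
NumericVector mesh_signed_distance_cpp(NumericMatrix V, IntegerMatrix F, NumericMatrix Q) {
  MeshSDF sdf(V, F);
  NumericVector out(Q.nrow());
  for (int i = 0; i < Q.nrow(); ++i)
    out[i] = sdf.phi(Vec3(Q(i, 0), Q(i, 1), Q(i, 2)));
  return out;
}

// index (1-based) of nearest surface triangle per query point
// [[Rcpp::export]]
IntegerVector nearest_triangle_cpp(NumericMatrix V, IntegerMatrix F, NumericMatrix Q) {
  MeshSDF sdf(V, F);
  IntegerVector out(Q.nrow());
  for (int i = 0; i < Q.nrow(); ++i) {
    int f = -1;
    sdf.unsigned_dist(Vec3(Q(i, 0), Q(i, 1), Q(i, 2)), &f);
    out[i] = f + 1;
  }
  return out;
}

// boundary faces of a tet mesh, outward oriented, with owning tet
// [[Rcpp::export]]
List boundary_faces_cpp(NumericMatrix V, IntegerMatrix T) {
  // faces of a positively-oriented tet (0-based local): outward orderings
  static const int ftab[4][3] = {{0, 2, 1}, {0, 1, 3}, {1, 2, 3}, {0, 3, 2}};
  std::unordered_map<uint64_t, std::pair<int, int>> count;  // key -> (count, tet*4+face)
  auto key3 = [](int a, int b, int c) {
    int v[3] = {a, b, c};
    std::sort(v, v + 3);
    return ((uint64_t)v[0] << 42) ^ ((uint64_t)v[1] << 21) ^ (uint64_t)v[2];
  };
  int nt = T.nrow();
  for (int t = 0; t < nt; ++t)
    for (int f = 0; f < 4; ++f) {
      int a = T(t, ftab[f][0]) - 1, b = T(t, ftab[f][1]) - 1, c = T(t, ftab[f][2]) - 1;
      uint64_t k = key3(a, b, c);
      auto it = count.find(k);
      if (it == count.end())
        count[k] = {1, t * 4 + f};
      else
        it->second.first++;
    }
  std::vector<int> tri, owner;
  for (auto& kv : count)
    if (kv.second.first == 1) {
      int t = kv.second.second / 4, f = kv.second.second % 4;
      tri.push_back(T(t, ftab[f][0]));
      tri.push_back(T(t, ftab[f][1]));
      tri.push_back(T(t, ftab[f][2]));
      owner.push_back(t + 1);
    }
  int nb = (int)owner.size();
  IntegerMatrix Fout(nb, 3);
  IntegerVector own(nb);
  for (int i = 0; i < nb; ++i) {
    Fout(i, 0) = tri[3 * i];
    Fout(i, 1) = tri[3 * i + 1];
    Fout(i, 2) = tri[3 * i + 2];
    own[i] = owner[i];
  }
  return List::create(_["faces"] = Fout, _["owner"] = own);
}

// [[Rcpp::export]]
double max_pairwise_distance_cpp(NumericMatrix V) {
  double best = 0;
  int n = V.nrow();
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = V(i, 0) - V(j, 0), dy = V(i, 1) - V(j, 1), dz = V(i, 2) - V(j, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d > best) best = d;
    }
  return std::sqrt(best);
}
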