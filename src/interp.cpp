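// Point location and P1 interpolation on tetrahedral meshes, with a
// uniform-grid accelerator kept alive as an external pointer.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Locator {
  NumericMatrix V;
  IntegerMatrix T;
  double lo[3], cell;
  int nd[3];
  std::vector<std::vector<int>> bins;

  Locator(NumericMatrix V_, IntegerMatrix T_) : V(V_), T(T_) {
    double hi[3];
    for (int c = 0; c < 3; ++c) { lo[c] = R_PosInf; hi[c] = R_NegInf; }
    for (int i = 0; i < V.nrow(); ++i)
      for (int c = 0; c < 3; ++c) {
        lo[c] = std::min(lo[c], V(i, c));
        hi[c] = std::max(hi[c], V(i, c));
      }
    double vol = std::max((hi[0] - lo[0]) * (hi[1] - lo[1]) * (hi[2] - lo[2]), 1e-300);
    cell = std::cbrt(vol / std::max(1, T.nrow())) * 2.0;
    for (int c = 0; c < 3; ++c)
      nd[c] = std::max(1, (int)((hi[c] - lo[c]) / cell) + 1);
    bins.resize((size_t)nd[0] * nd[1] * nd[2]);
    for (int t = 0; t < T.nrow(); ++t) {
      double b0[3] = {R_PosInf, R_PosInf, R_PosInf}, b1[3] = {R_NegInf, R_NegInf, R_NegInf};
      for (int k = 0; k < 4; ++k) {
        int v = T(t, k) - 1;
        for (int c = 0; c < 3; ++c) {
          b0[c] = std::min(b0[c], V(v, c));
          b1[c] = std::max(b1[c], V(v, c));
        }
      }
      int i0[3], i1[3];
      for (int c = 0; c < 3; ++c) {
        i0[c] = std::max(0, (int)((b0[c] - lo[c]) / cell));
        i1[c] = std::min(nd[c] - 1, (int)((b1[c] - lo[c]) / cell));
      }
      for (int i = i0[0]; i <= i1[0]; ++i)
        for (int j = i0[1]; j <= i1[1]; ++j)
          for (int k = i0[2]; k <= i1[2]; ++k)
            bins[((size_t)i * nd[1] + j) * nd[2] + k].push_back(t);
    }
  }

  // returns tet index (0-based) or -1; fills barycentric coords
  int locate(const double* q, double* bc) const {
    int ix[3];
    for (int c = 0; c < 3; ++c) {
      ix[c] = (int)((q[c] - lo[c]) / cell);
      if (ix[c] < 0 || ix[c] >= nd[c]) return -1;
    }
    const std::vector<int>& cand = bins[((size_t)ix[0] * nd[1] + ix[1]) * nd[2] + ix[2]];
    for (int t : cand) {
      int n0 = T(t, 0) - 1, n1 = T(t, 1) - 1, n2 = T(t, 2) - 1, n3 = T(t, 3) - 1;
      double a[3], b[3], cc[3], d[3];
      for (int c = 0; c < 3; ++c) {
        a[c] = V(n1, c) - V(n0, c);
        b[c] = V(n2, c) - V(n0, c);
        cc[c] = V(n3, c) - V(n0, c);
        d[c] = q[c] - V(n0, c);
      }
      double det = a[0] * (b[1] * cc[2] - b[2] * cc[1]) - a[1] * (b[0] * cc[2] - b[2] * cc[0]) +
                   a[2] * (b[0] * cc[1] - b[1] * cc[0]);
      if (std::fabs(det) < 1e-300) continue;
      double l1 = (d[0] * (b[1] * cc[2] - b[2] * cc[1]) - d[1] * (b[0] * cc[2] - b[2] * cc[0]) +
                   d[2] * (b[0] * cc[1] - b[1] * cc[0])) / det;
      double l2 = (a[0] * (d[1] * cc[2] - d[2] * cc[1]) - a[1] * (d[0] * cc[2] - d[2] * cc[0]) +
                   a[2] * (d[0] * cc[1] - d[1] * cc[0])) / det;
      double l3 = (a[0] * (b[1] * d[2] - b[2] * d[1]) - a[1] * (b[0] * d[2] - b[2] * d[0]) +
                   a[2] * (b[0] * d[1] - b[1] * d[0])) / det;
      double l0 = 1.0 - l1 - l2 - l3;
      double tol = -1e-9;
      if (l0 >= tol && l1 >= tol && l2 >= tol && l3 >= tol) {
        bc[0] = l0; bc[1] = l1; bc[2] = l2; bc[3] = l3;
        return t;
      }
    }
    return -1;
  }
};

}  // namespace

// [[Rcpp::export]]
SEXP make_locator_cpp(NumericMatrix V, IntegerMatrix T) {
  Rcpp::XPtr<Locator> p(new Locator(V, T), true);
  return p;
}

// interpolate nodal fields (N x m) at query points; NA outside the mesh
// [[Rcpp::export]]
NumericMatrix interp_field_cpp(SEXP loc, NumericMatrix field, NumericMatrix Q) {
  Rcpp::XPtr<Locator> p(loc);
  int m = field.ncol();
  NumericMatrix out(Q.nrow(), m);
  double bc[4], q[3];
  for (int i = 0; i < Q.nrow(); ++i) {
    for (int c = 0; c < 3; ++c) q[c] = Q(i, c);
    int t = p->locate(q, bc);
    if (t < 0) {
      for (int c = 0; c < m; ++c) out(i, c) = NA_REAL;
    } else {
      for (int c = 0; c < m; ++c) {
        double s = 0;
        for (int k = 0; k < 4; ++k) s += bc[k] * field(p->T(t, k) - 1, c);
        out(i, c) = s;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector locate_points_cpp(SEXP loc, NumericMatrix Q) {
  Rcpp::XPtr<Locator> p(loc);
  IntegerVector out(Q.nrow());
  double bc[4], q[3];
  for (int i = 0; i < Q.nrow(); ++i) {
    for (int c = 0; c < 3; ++c) q[c] = Q(i, c);
    out[i] = p->locate(q, bc) + 1;  // 0 when outside
  }
  return out;
}
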