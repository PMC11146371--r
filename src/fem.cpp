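// Incompressible Newtonian Navier-Stokes on tetrahedral meshes.
//
// Discretization: the MINI element (P1 velocity enriched by a cubic
// bubble, P1 pressure) with the bubble statically condensed, which
// yields a P1-P1 pair plus an element-wise pressure-Laplacian
// stabilization with coefficient tau_e = Ib^2 / (mu * kb), where
// Ib = int_K b dV and kb = int_K |grad b|^2 dV for the bubble
// b = 256 l1 l2 l3 l4.  The bubble is condensed against the Stokes
// operator only; its convective and transient couplings are dropped.
//
// Convection is linearly implicit: the advecting field is the previous
// Picard iterate (steady) or the BDF-extrapolated previous solution
// (transient), with a Temam skew-symmetrization term for stability.
// The momentum viscous term uses the gradient form mu (grad u, grad v),
// whose natural outlet condition mu du/dn - p n = 0 reproduces fully
// developed outflow exactly.
//
// Linear systems are solved by Eigen's SparseLU; the symbolic pattern
// is analysed once and refactorized per step / Picard iterate.
//
// Wall traction is recovered by the consistent-flux method: the
// unconstrained momentum residual at wall nodes equals the weak
// boundary term \oint (mu grad u . n - p n) . v, so dividing by the
// lumped wall mass gives a superconvergent nodal traction.

// [[Rcpp::depends(RcppEigen)]]
#include <RcppEigen.h>
#include <Eigen/SparseLU>
#include <vector>
#include <cmath>

using namespace Rcpp;
typedef Eigen::SparseMatrix<double> SpMat;
typedef Eigen::Triplet<double> Trip;

namespace {

struct FE {
  int N, NT;
  const NumericMatrix& V;
  const IntegerMatrix& T;
  double mu, rho;
  std::vector<double> vol;       // tet volume
  std::vector<double> grad;      // NT x 4 x 3 basis gradients
  std::vector<double> taue;      // bubble stabilization coefficient

  FE(const NumericMatrix& V_, const IntegerMatrix& T_, double mu_, double rho_)
      : N(V_.nrow()), NT(T_.nrow()), V(V_), T(T_), mu(mu_), rho(rho_) {
    vol.resize(NT);
    grad.resize((size_t)NT * 12);
    taue.resize(NT);
    const double cIb = 256.0 * 6.0 / 5040.0;       // int b = cIb * V
    const double ckb = 65536.0 * 24.0 / 362880.0;  // int |grad b|^2 = ckb * V * sum |grad l_i|^2
    for (int e = 0; e < NT; ++e) {
      int n[4];
      for (int k = 0; k < 4; ++k) n[k] = T(e, k) - 1;
      double x[4], y[4], z[4];
      for (int k = 0; k < 4; ++k) {
        x[k] = V(n[k], 0); y[k] = V(n[k], 1); z[k] = V(n[k], 2);
      }
      double a1 = x[1] - x[0], a2 = y[1] - y[0], a3 = z[1] - z[0];
      double b1 = x[2] - x[0], b2 = y[2] - y[0], b3 = z[2] - z[0];
      double c1 = x[3] - x[0], c2 = y[3] - y[0], c3 = z[3] - z[0];
      double det = a1 * (b2 * c3 - b3 * c2) - a2 * (b1 * c3 - b3 * c1) + a3 * (b1 * c2 - b2 * c1);
      vol[e] = det / 6.0;
      if (vol[e] <= 0) stop("non-positive tetrahedron volume in solver mesh");
      // gradients of barycentric coordinates: rows of inverse Jacobian
      double inv[3][3];
      inv[0][0] = (b2 * c3 - b3 * c2) / det;
      inv[0][1] = (b3 * c1 - b1 * c3) / det;
      inv[0][2] = (b1 * c2 - b2 * c1) / det;
      inv[1][0] = (a3 * c2 - a2 * c3) / det;
      inv[1][1] = (a1 * c3 - a3 * c1) / det;
      inv[1][2] = (a2 * c1 - a1 * c2) / det;
      inv[2][0] = (a2 * b3 - a3 * b2) / det;
      inv[2][1] = (a3 * b1 - a1 * b3) / det;
      inv[2][2] = (a1 * b2 - a2 * b1) / det;
      double* g = &grad[(size_t)e * 12];
      double sg = 0;
      for (int c = 0; c < 3; ++c) {
        g[1 * 3 + c] = inv[0][c];
        g[2 * 3 + c] = inv[1][c];
        g[3 * 3 + c] = inv[2][c];
        g[0 * 3 + c] = -(inv[0][c] + inv[1][c] + inv[2][c]);
      }
      for (int k = 0; k < 4; ++k)
        sg += g[k * 3] * g[k * 3] + g[k * 3 + 1] * g[k * 3 + 1] + g[k * 3 + 2] * g[k * 3 + 2];
      double Ib = cIb * vol[e];
      double kb = ckb * vol[e] * sg;
      taue[e] = Ib * Ib / (mu * kb);
    }
  }

  // dof layout: node n -> 4n+c (c=0..2 velocity), 4n+3 pressure
  // assemble the constrained system for advecting field w and time factor
  // a0rdt = alpha0 * rho / dt (0 for steady)
  void assemble(const std::vector<double>& w, double a0rdt,
                const std::vector<char>& fixed, std::vector<Trip>& trip) const {
    trip.clear();
    trip.reserve((size_t)NT * 170 + N);
    for (int e = 0; e < NT; ++e) {
      int n[4];
      for (int k = 0; k < 4; ++k) n[k] = T(e, k) - 1;
      const double* g = &grad[(size_t)e * 12];
      double Ve = vol[e];
      // element advecting field and its divergence
      double wl[4][3], sw[3] = {0, 0, 0}, divw = 0;
      for (int k = 0; k < 4; ++k)
        for (int c = 0; c < 3; ++c) {
          wl[k][c] = w[(size_t)3 * n[k] + c];
          sw[c] += wl[k][c];
          divw += wl[k][c] * g[k * 3 + c];
        }
      for (int i = 0; i < 4; ++i) {
        int ri = n[i];
        for (int j = 0; j < 4; ++j) {
          int rj = n[j];
          double gij = g[i * 3] * g[j * 3] + g[i * 3 + 1] * g[j * 3 + 1] + g[i * 3 + 2] * g[j * 3 + 2];
          double mij = Ve * (i == j ? 2.0 : 1.0) / 20.0;
          // int phi_i (w . grad phi_j) = (V/20) grad phi_j . (sw + w_i)
          double conv = 0;
          for (int c = 0; c < 3; ++c) conv += g[j * 3 + c] * (sw[c] + wl[i][c]);
          conv *= rho * Ve / 20.0;
          conv += 0.5 * rho * divw * mij;  // Temam term
          double auu = mu * gij * Ve + conv + a0rdt * mij;
          for (int c = 0; c < 3; ++c) {
            int r = 4 * ri + c, cc = 4 * rj + c;
            if (!fixed[r]) trip.push_back(Trip(r, cc, auu));
          }
          // momentum-pressure: -(V/4) dphi_i/dc * p_j
          for (int c = 0; c < 3; ++c) {
            int r = 4 * ri + c;
            if (!fixed[r]) trip.push_back(Trip(r, 4 * rj + 3, -(Ve / 4.0) * g[i * 3 + c]));
          }
          // continuity: (V/4) dphi_j/dc * u_{j,c} + tau (grad p, grad q)
          for (int c = 0; c < 3; ++c)
            trip.push_back(Trip(4 * ri + 3, 4 * rj + c, (Ve / 4.0) * g[j * 3 + c]));
          trip.push_back(Trip(4 * ri + 3, 4 * rj + 3, taue[e] * gij));
        }
      }
    }
    for (int i = 0; i < 4 * N; ++i)
      if (fixed[i]) trip.push_back(Trip(i, i, 1.0));
  }

  // momentum residual of the unconstrained equations at given nodes;
  // rhsu = alpha1 u^{n-1} + alpha2 u^{n-2} (per node, 3 comps), may be empty
  void residual_at(const std::vector<double>& x, const std::vector<double>& w,
                   double a0rdt, double rdt, const std::vector<double>& rhsu,
                   const std::vector<int>& nodes, std::vector<double>& res) const {
    std::vector<int> mark(N, -1);
    for (size_t i = 0; i < nodes.size(); ++i) mark[nodes[i]] = (int)i;
    res.assign(nodes.size() * 3, 0.0);
    for (int e = 0; e < NT; ++e) {
      int n[4];
      bool touch = false;
      for (int k = 0; k < 4; ++k) {
        n[k] = T(e, k) - 1;
        if (mark[n[k]] >= 0) touch = true;
      }
      if (!touch) continue;
      const double* g = &grad[(size_t)e * 12];
      double Ve = vol[e];
      double wl[4][3], sw[3] = {0, 0, 0}, divw = 0, psum = 0;
      for (int k = 0; k < 4; ++k) {
        psum += x[(size_t)4 * n[k] + 3];
        for (int c = 0; c < 3; ++c) {
          wl[k][c] = w[(size_t)3 * n[k] + c];
          sw[c] += wl[k][c];
          divw += wl[k][c] * g[k * 3 + c];
        }
      }
      for (int i = 0; i < 4; ++i) {
        int mi = mark[n[i]];
        if (mi < 0) continue;
        for (int j = 0; j < 4; ++j) {
          double gij = g[i * 3] * g[j * 3] + g[i * 3 + 1] * g[j * 3 + 1] + g[i * 3 + 2] * g[j * 3 + 2];
          double mij = Ve * (i == j ? 2.0 : 1.0) / 20.0;
          double conv = 0;
          for (int c = 0; c < 3; ++c) conv += g[j * 3 + c] * (sw[c] + wl[i][c]);
          conv *= rho * Ve / 20.0;
          conv += 0.5 * rho * divw * mij;
          double auu = mu * gij * Ve + conv + a0rdt * mij;
          for (int c = 0; c < 3; ++c) {
            res[(size_t)3 * mi + c] += auu * x[(size_t)4 * n[j] + c];
            if (!rhsu.empty())
              res[(size_t)3 * mi + c] += rdt * mij * rhsu[(size_t)3 * n[j] + c];
          }
        }
        for (int c = 0; c < 3; ++c)
          res[(size_t)3 * mi + c] += -(Ve / 4.0) * g[i * 3 + c] * psum;
      }
    }
  }

  double kinetic_energy(const std::vector<double>& x) const {
    double ke = 0;
    for (int e = 0; e < NT; ++e) {
      int n[4];
      for (int k = 0; k < 4; ++k) n[k] = T(e, k) - 1;
      double Ve = vol[e];
      for (int c = 0; c < 3; ++c)
        for (int i = 0; i < 4; ++i)
          for (int j = 0; j < 4; ++j)
            ke += 0.5 * rho * Ve * (i == j ? 2.0 : 1.0) / 20.0 *
                  x[(size_t)4 * n[i] + c] * x[(size_t)4 * n[j] + c];
    }
    return ke;
  }
};

void set_dirichlet(std::vector<double>& b, const IntegerVector& dn,
                   const NumericMatrix& dbase, double scale) {
  for (int i = 0; i < dn.size(); ++i)
    for (int c = 0; c < 3; ++c)
      b[(size_t)4 * dn[i] + c] = dbase(i, c) * scale;
}

}  // namespace

// [[Rcpp::export]]
List ns_solve_cpp(NumericMatrix V, IntegerMatrix T, double mu, double rho,
                  IntegerVector dir_nodes, NumericMatrix dir_base,
                  bool steady, NumericVector scale_steps, double dt, int bdf,
                  int store_from, double tol, int maxit, double relax,
                  IntegerVector wall_nodes, NumericVector wall_mass) {
  FE fe(V, T, mu, rho);
  int N = fe.N, ndof = 4 * N;
  std::vector<char> fixed(ndof, 0);
  for (int i = 0; i < dir_nodes.size(); ++i)
    for (int c = 0; c < 3; ++c) fixed[(size_t)4 * dir_nodes[i] + c] = 1;

  std::vector<int> wn(wall_nodes.begin(), wall_nodes.end());
  std::vector<Trip> trip;
  SpMat A(ndof, ndof);
  Eigen::SparseLU<SpMat> lu;
  bool analyzed = false;
  std::vector<double> x(ndof, 0.0), w((size_t)3 * N, 0.0);
  std::vector<double> b(ndof, 0.0), res;

  auto factor_solve = [&](double a0rdt, const std::vector<double>& rhs) {
    fe.assemble(w, a0rdt, fixed, trip);
    A.setFromTriplets(trip.begin(), trip.end());
    if (!analyzed) { lu.analyzePattern(A); analyzed = true; }
    lu.factorize(A);
    if (lu.info() != Eigen::Success) stop("sparse LU factorization failed");
    Eigen::Map<const Eigen::VectorXd> bb(rhs.data(), ndof);
    Eigen::VectorXd xx = lu.solve(bb);
    std::copy(xx.data(), xx.data() + ndof, x.begin());
  };

  auto pack_uvel = [&](std::vector<double>& dst) {
    dst.resize((size_t)3 * N);
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < 3; ++c) dst[(size_t)3 * n + c] = x[(size_t)4 * n + c];
  };

  auto traction = [&](double a0rdt, double rdt, const std::vector<double>& rhsu,
                      NumericMatrix& out) {
    fe.residual_at(x, w, a0rdt, rdt, rhsu, wn, res);
    for (size_t i = 0; i < wn.size(); ++i)
      for (int c = 0; c < 3; ++c)
        out(i, c) = res[3 * i + c] / wall_mass[i];
  };

  if (steady) {
    NumericVector hist(maxit);
    int it = 0;
    double change = NA_REAL, prev_change = R_PosInf;
    std::vector<double> uprev;
    for (; it < maxit; ++it) {
      std::fill(b.begin(), b.end(), 0.0);
      set_dirichlet(b, dir_nodes, dir_base, 1.0);
      factor_solve(0.0, b);
      std::vector<double> unew;
      pack_uvel(unew);
      double num = 0, den = 1e-300;
      if (!uprev.empty()) {
        for (size_t i = 0; i < unew.size(); ++i) {
          num = std::max(num, std::fabs(unew[i] - uprev[i]));
          den = std::max(den, std::fabs(unew[i]));
        }
        change = num / den;
      }
      hist[it] = change;
      // adaptive under-relaxation: back off only when the sweep-to-sweep
      // change stops contracting (Picard oscillation at higher Re)
      if (it >= 3 && change > 1.1 * prev_change) relax = std::max(0.4, 0.6 * relax);
      else if (it >= 3 && change > 0.97 * prev_change) relax = std::max(0.5, 0.85 * relax);
      if (!ISNA(change)) prev_change = change;
      if (uprev.empty() || relax >= 1.0) {
        w = unew;
      } else {
        for (size_t i = 0; i < w.size(); ++i)
          w[i] = relax * unew[i] + (1.0 - relax) * w[i];
      }
      uprev = unew;
      if (it >= 1 && change < tol) { ++it; break; }
    }
    // recover traction consistently with the final advecting field
    NumericMatrix tr(wn.size(), 3);
    traction(0.0, 0.0, std::vector<double>(), tr);
    NumericMatrix U(N, 3);
    NumericVector P(N);
    for (int n = 0; n < N; ++n) {
      for (int c = 0; c < 3; ++c) U(n, c) = x[(size_t)4 * n + c];
      P[n] = x[(size_t)4 * n + 3];
    }
    return List::create(_["u"] = U, _["p"] = P, _["traction"] = tr,
                        _["iterations"] = it,
                        _["change"] = hist[Range(0, std::max(0, it - 1))]);
  }

  // ---- transient -----------------------------------------------------------
  int nsteps = scale_steps.size();
  int nstore = std::max(0, nsteps - store_from);
  List Ust(nstore), Pst(nstore), Trst(nstore);
  NumericVector ketrace(nsteps);
  std::vector<double> um1((size_t)3 * N, 0.0), um2((size_t)3 * N, 0.0), rhsu((size_t)3 * N);
  for (int k = 0; k < nsteps; ++k) {
    double a0, a1, a2;
    if (k == 0 || bdf == 1) { a0 = 1.0; a1 = -1.0; a2 = 0.0; }
    else { a0 = 1.5; a1 = -2.0; a2 = 0.5; }
    double a0rdt = a0 * rho / dt, rdt = rho / dt;
    // advecting field: BDF-consistent extrapolation of previous solutions
    if (k == 0) {
      std::fill(w.begin(), w.end(), 0.0);
    } else if (k == 1 || bdf == 1) {
      w = um1;
    } else {
      for (size_t i = 0; i < w.size(); ++i) w[i] = 2.0 * um1[i] - um2[i];
    }
    for (size_t i = 0; i < rhsu.size(); ++i) rhsu[i] = a1 * um1[i] + a2 * um2[i];
    // rhs: -(rho/dt) M (a1 u^{n-1} + a2 u^{n-2}) via element mass
    std::fill(b.begin(), b.end(), 0.0);
    for (int e = 0; e < fe.NT; ++e) {
      int n[4];
      for (int q = 0; q < 4; ++q) n[q] = T(e, q) - 1;
      double Ve = fe.vol[e];
      for (int i = 0; i < 4; ++i) {
        if (fixed[(size_t)4 * n[i]]) continue;
        for (int j = 0; j < 4; ++j) {
          double mij = Ve * (i == j ? 2.0 : 1.0) / 20.0;
          for (int c = 0; c < 3; ++c)
            b[(size_t)4 * n[i] + c] -= rdt * mij * rhsu[(size_t)3 * n[j] + c];
        }
      }
    }
    set_dirichlet(b, dir_nodes, dir_base, scale_steps[k]);
    factor_solve(a0rdt, b);
    double ke = fe.kinetic_energy(x);
    ketrace[k] = ke;
    if (!std::isfinite(ke) || ke > 1e12)
      stop("transient solve diverged (kinetic energy blow-up at step %d)", k + 1);
    if (k >= store_from) {
      NumericMatrix U(N, 3);
      NumericVector P(N);
      for (int n = 0; n < N; ++n) {
        for (int c = 0; c < 3; ++c) U(n, c) = x[(size_t)4 * n + c];
        P[n] = x[(size_t)4 * n + 3];
      }
      NumericMatrix tr(wn.size(), 3);
      traction(a0rdt, rdt, rhsu, tr);
      Ust[k - store_from] = U;
      Pst[k - store_from] = P;
      Trst[k - store_from] = tr;
    }
    um2 = um1;
    pack_uvel(um1);
    if ((k + 1) % 25 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["u_steps"] = Ust, _["p_steps"] = Pst,
                      _["traction_steps"] = Trst, _["kinetic_energy"] = ketrace);
}
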