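#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gauss-Seidel / SOR sweeps for the 7-point finite-difference
// discretization of the linearized Poisson-Boltzmann equation
//
//   div(eps grad phi) - kap2 phi = -b
//
// on a regular grid with Dirichlet boundary values already stored in
// phi.  eps is node-centred; face values use the harmonic mean.  src
// holds h^2 * b (so the update is purely algebraic in grid units);
// kap2h2 holds h^2 * eps_out * kappa^2 * accessibility.  Returns the
// converged field, the iteration count and the final relative residual
// ||r||_2 / ||h^2 b||_2 (or the absolute residual norm if b == 0).
// [[Rcpp::export]]
List sor_lpbe_cpp(NumericVector phi0, NumericVector eps,
                  NumericVector kap2h2, NumericVector src,
                  IntegerVector dims, double tol, int max_iter,
                  double omega) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector phi = clone(phi0);
  double *p = REAL(phi);
  const double *e = REAL(eps), *k2 = REAL(kap2h2), *b = REAL(src);
  const R_xlen_t n = phi.size();

  double bnorm = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) bnorm += b[i] * b[i];
  bnorm = std::sqrt(bnorm);
  const double denom = bnorm > 0 ? bnorm : 1.0;

  auto hm = [](double a, double c) { return 2.0 * a * c / (a + c); };
  const int sx = 1, sy = nx, sz = nx * ny;

  double rel = R_PosInf;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    double rss = 0.0;
    for (int k = 1; k < nz - 1; ++k) {
      for (int j = 1; j < ny - 1; ++j) {
        R_xlen_t idx = (R_xlen_t)sz * k + (R_xlen_t)sy * j + 1;
        for (int i = 1; i < nx - 1; ++i, ++idx) {
          const double ec = e[idx];
          const double exm = hm(ec, e[idx - sx]), exp_ = hm(ec, e[idx + sx]);
          const double eym = hm(ec, e[idx - sy]), eyp = hm(ec, e[idx + sy]);
          const double ezm = hm(ec, e[idx - sz]), ezp = hm(ec, e[idx + sz]);
          const double A = exm + exp_ + eym + eyp + ezm + ezp + k2[idx];
          const double num = exm * p[idx - sx] + exp_ * p[idx + sx] +
                             eym * p[idx - sy] + eyp * p[idx + sy] +
                             ezm * p[idx - sz] + ezp * p[idx + sz] + b[idx];
          const double res = num - A * p[idx];
          rss += res * res;
          p[idx] += omega * res / A;
        }
      }
    }
    rel = std::sqrt(rss) / denom;
    if (rel < tol) break;
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["phi"] = phi, _["iterations"] = std::min(it, max_iter),
                      _["residual"] = rel, _["converged"] = rel < tol);
}

// Mark grid nodes lying within per-atom spheres: used to build the
// dielectric map (radius) and the ion-accessibility map (radius +
// probe).  field is modified in place conceptually but R semantics are
// preserved by cloning.
// [[Rcpp::export]]
NumericVector paint_spheres_cpp(NumericVector field, NumericVector origin,
                                double h, IntegerVector dims,
                                NumericMatrix xyz, NumericVector radii,
                                double value) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out = clone(field);
  double *f = REAL(out);
  for (int a = 0; a < xyz.nrow(); ++a) {
    const double r = radii[a];
    if (r <= 0) continue;
    const double r2 = r * r;
    const double cx = xyz(a, 0), cy = xyz(a, 1), cz = xyz(a, 2);
    int i0 = (int)std::ceil((cx - r - origin[0]) / h);
    int i1 = (int)std::floor((cx + r - origin[0]) / h);
    int j0 = (int)std::ceil((cy - r - origin[1]) / h);
    int j1 = (int)std::floor((cy + r - origin[1]) / h);
    int k0 = (int)std::ceil((cz - r - origin[2]) / h);
    int k1 = (int)std::floor((cz + r - origin[2]) / h);
    if (i0 < 0) i0 = 0; if (i1 > nx - 1) i1 = nx - 1;
    if (j0 < 0) j0 = 0; if (j1 > ny - 1) j1 = ny - 1;
    if (k0 < 0) k0 = 0; if (k1 > nz - 1) k1 = nz - 1;
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + h * k - cz;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + h * j - cy;
        const double dyz = dy * dy + dz * dz;
        if (dyz > r2) continue;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + h * i - cx;
          if (dx * dx + dyz <= r2)
            f[(R_xlen_t)(nx * ny) * k + (R_xlen_t)nx * j + i] = value;
        }
      }
    }
  }
  return out;
}

// Running minimum, over atoms, of (distance to atom centre - atom
// radius) at every grid node, evaluated only within reach Angstrom of
// each atom surface (values beyond every atom's reach stay at their
// initial +Inf).  This is the workhorse for PIPSA-style skin masks.
// [[Rcpp::export]]
NumericVector surface_distance_cpp(NumericVector origin, double h,
                                   IntegerVector dims, NumericMatrix xyz,
                                   NumericVector radii, double reach) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz, R_PosInf);
  double *f = REAL(out);
  for (int a = 0; a < xyz.nrow(); ++a) {
    const double r = radii[a], ext = r + reach;
    const double cx = xyz(a, 0), cy = xyz(a, 1), cz = xyz(a, 2);
    int i0 = (int)std::ceil((cx - ext - origin[0]) / h);
    int i1 = (int)std::floor((cx + ext - origin[0]) / h);
    int j0 = (int)std::ceil((cy - ext - origin[1]) / h);
    int j1 = (int)std::floor((cy + ext - origin[1]) / h);
    int k0 = (int)std::ceil((cz - ext - origin[2]) / h);
    int k1 = (int)std::floor((cz + ext - origin[2]) / h);
    if (i0 < 0) i0 = 0; if (i1 > nx - 1) i1 = nx - 1;
    if (j0 < 0) j0 = 0; if (j1 > ny - 1) j1 = ny - 1;
    if (k0 < 0) k0 = 0; if (k1 > nz - 1) k1 = nz - 1;
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + h * k - cz;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + h * j - cy;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + h * i - cx;
          const double sd = std::sqrt(dx * dx + dy * dy + dz * dz) - r;
          R_xlen_t idx = (R_xlen_t)(nx * ny) * k + (R_xlen_t)nx * j + i;
          if (sd < f[idx]) f[idx] = sd;
        }
      }
    }
  }
  return out;
}
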