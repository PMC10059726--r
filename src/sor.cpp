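#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Successive over-relaxation sweep solver for the variable-dielectric
// finite-difference Poisson(-Boltzmann, linearized) problem
//   sum_faces eps_f (phi_nb - phi_0) - lam_0 phi_0 + src_0 = 0
// on an nx*ny*nz node grid with Dirichlet boundary values already stored
// in phi. epsx/epsy/epsz hold face dielectrics between node (i,j,k) and
// its +x/+y/+z neighbour. lam carries the kappa^2 h^2 eps term. Returns
// [iterations, last max update].
// [[Rcpp::export]]
NumericVector sor_poisson(NumericVector phi, NumericVector epsx,
                          NumericVector epsy, NumericVector epsz,
                          NumericVector lam, NumericVector src,
                          int nx, int ny, int nz,
                          double omega, double tol, int max_iter) {
  double *p = REAL(phi);
  const double *ex = REAL(epsx), *ey = REAL(epsy), *ez = REAL(epsz);
  const double *lm = REAL(lam), *sc = REAL(src);
  const int sx = 1, sy = nx, sz = nx * ny;
  double maxupd = 0.0;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    maxupd = 0.0;
    for (int k = 1; k < nz - 1; ++k)
      for (int j = 1; j < ny - 1; ++j) {
        int base = j * sy + k * sz;
        for (int i = 1; i < nx - 1; ++i) {
          int id = i + base;
          double exm = ex[id - sx], exp_ = ex[id];
          double eym = ey[id - sy], eyp = ey[id];
          double ezm = ez[id - sz], ezp = ez[id];
          double denom = exm + exp_ + eym + eyp + ezm + ezp + lm[id];
          double rhs = exm * p[id - sx] + exp_ * p[id + sx] +
                       eym * p[id - sy] + eyp * p[id + sy] +
                       ezm * p[id - sz] + ezp * p[id + sz] + sc[id];
          double nv = (1.0 - omega) * p[id] + omega * rhs / denom;
          double d = std::fabs(nv - p[id]);
          if (d > maxupd) maxupd = d;
          p[id] = nv;
        }
      }
    if (maxupd < tol) break;
  }
  return NumericVector::create((double)std::min(it, max_iter), maxupd);
}
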