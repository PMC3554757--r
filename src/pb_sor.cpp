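#include <Rcpp.h>
using namespace Rcpp;

// Successive over-relaxation sweep solver for the linearized
// Poisson-Boltzmann 7-point stencil:
//   sum_f eps_f (phi_nb - phi0)/h^2 - lambda0/h^2 * phi0 = -src0/h^2
// rearranged per node to
//   phi0 = (sum_f eps_f phi_nb + src0) / (sum_f eps_f + lambda0)
// where src = 4*pi*k_e*q/h (kcal/(mol e) * dielectric units) and
// lambda = eps_w * kappa^2 * h^2 on solvent nodes, 0 inside the solute.
// Face dielectrics epsx/epsy/epsz sit between node (i,j,k) and its +x/+y/+z
// neighbour.  The outermost node layer is held fixed (Dirichlet boundary).
// [[Rcpp::export]]
List pb_sor(NumericVector phi_, NumericVector epsx_, NumericVector epsy_,
            NumericVector epsz_, NumericVector lambda_, NumericVector src_,
            IntegerVector dims, double omega, double tol, int max_iter) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> phi(phi_.begin(), phi_.end());
  const double *ex = epsx_.begin(), *ey = epsy_.begin(), *ez = epsz_.begin();
  const double *lam = lambda_.begin(), *src = src_.begin();
  const int sx = 1, sy = nx, sz = nx * ny;
  double maxdiff = 0.0;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    maxdiff = 0.0;
    for (int k = 1; k < nz - 1; ++k) {
      for (int j = 1; j < ny - 1; ++j) {
        int idx = sx + j * sy + k * sz;  // i = 1
        for (int i = 1; i < nx - 1; ++i, idx += sx) {
          double exm = ex[idx - sx], exp_ = ex[idx];
          double eym = ey[idx - sy], eyp = ey[idx];
          double ezm = ez[idx - sz], ezp = ez[idx];
          double denom = exm + exp_ + eym + eyp + ezm + ezp + lam[idx];
          double num = exm * phi[idx - sx] + exp_ * phi[idx + sx] +
                       eym * phi[idx - sy] + eyp * phi[idx + sy] +
                       ezm * phi[idx - sz] + ezp * phi[idx + sz] + src[idx];
          double nv = (1.0 - omega) * phi[idx] + omega * num / denom;
          double d = std::fabs(nv - phi[idx]);
          if (d > maxdiff) maxdiff = d;
          phi[idx] = nv;
        }
      }
    }
    if (maxdiff < tol) break;
  }
  return List::create(_["phi"] = NumericVector(phi.begin(), phi.end()),
                      _["iterations"] = it,
                      _["residual"] = maxdiff,
                      _["converged"] = maxdiff < tol);
}
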