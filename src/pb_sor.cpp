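#include <Rcpp.h>
using namespace Rcpp;

// Red-black successive over-relaxation for the node-centered finite
// difference discretization of div(eps grad phi) = -4 pi k_c rho (+ Debye
// screening). For interior node c the update solves
//   sum_f eps_f (phi_nb - phi_c) + src_c - screen_c phi_c = 0
// where src_c = 4 pi k_c q_c / h and screen_c = eps kappa^2 h^2 on solvent
// nodes. Boundary (outermost) nodes hold fixed Dirichlet values.
//
// phi is a flat array in column-major order: idx = i + nx*(j + ny*k).
// epsx has extent (nx-1, ny, nz): face between nodes (i,.) and (i+1,.).

// [[Rcpp::export]]
List pb_sor(NumericVector phi_in, IntegerVector dims,
            NumericVector epsx, NumericVector epsy, NumericVector epsz,
            NumericVector src, NumericVector screen,
            double omega, double tol, int maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector phi = clone(phi_in);
  const double *ex = epsx.begin(), *ey = epsy.begin(), *ez = epsz.begin();
  const double *s = src.begin(), *sc = screen.begin();
  double *p = phi.begin();
  const int nxm = nx - 1;
  double maxdiff = R_PosInf;
  int it = 0;

  for (it = 1; it <= maxit; ++it) {
    maxdiff = 0.0;
    for (int color = 0; color < 2; ++color) {
      for (int k = 1; k < nz - 1; ++k) {
        for (int j = 1; j < ny - 1; ++j) {
          // update nodes with (i + j + k) % 2 == color
          int t = (j + k) & 1;
          int i0 = ((color ^ t) == 1) ? 1 : 2;
          int base = nx * (j + ny * k);
          for (int i = i0; i < nx - 1; i += 2) {
            int c = i + base;
            // face indices
            double exm = ex[(i - 1) + nxm * (j + ny * k)];
            double exp_ = ex[i + nxm * (j + ny * k)];
            double eym = ey[i + nx * ((j - 1) + (ny - 1) * k)];
            double eyp = ey[i + nx * (j + (ny - 1) * k)];
            double ezm = ez[i + nx * (j + ny * (k - 1))];
            double ezp = ez[i + nx * (j + ny * k)];
            double denom = exm + exp_ + eym + eyp + ezm + ezp + sc[c];
            double num = exm * p[c - 1] + exp_ * p[c + 1] +
                         eym * p[c - nx] + eyp * p[c + nx] +
                         ezm * p[c - nx * ny] + ezp * p[c + nx * ny] + s[c];
            double newv = (1.0 - omega) * p[c] + omega * num / denom;
            double d = std::abs(newv - p[c]);
            if (d > maxdiff) maxdiff = d;
            p[c] = newv;
          }
        }
      }
    }
    if (maxdiff < tol) break;
  }
  return List::create(_["phi"] = phi, _["iterations"] = std::min(it, maxit),
                      _["maxdiff"] = maxdiff,
                      _["converged"] = (maxdiff < tol));
}
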