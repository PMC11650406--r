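#include <Rcpp.h>
using namespace Rcpp;

// 7-point finite-volume stencil operator with symmetrically eliminated
// Dirichlet voxels.  x is zero at fixed voxels on entry; y is zeroed there
// on exit, so CG iterates stay in the free subspace.  Face conductances are
// stored per direction: gx has dim (nx-1, ny, nz) etc.
static void stencil_apply(int nx, int ny, int nz,
                          const double *gx, const double *gy, const double *gz,
                          const double *diag, const int *fixed,
                          const double *x, double *y) {
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  for (R_xlen_t i = 0; i < n; ++i) y[i] = diag[i] * x[i];

  for (int iz = 0; iz < nz; ++iz) {
    for (int iy = 0; iy < ny; ++iy) {
      R_xlen_t row = (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
      R_xlen_t grow = (R_xlen_t)(nx - 1) * (iy + (R_xlen_t)ny * iz);
      for (int ix = 0; ix < nx - 1; ++ix) {
        double g = gx[grow + ix];
        y[row + ix] -= g * x[row + ix + 1];
        y[row + ix + 1] -= g * x[row + ix];
      }
    }
  }
  for (int iz = 0; iz < nz; ++iz) {
    for (int iy = 0; iy < ny - 1; ++iy) {
      R_xlen_t row = (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
      R_xlen_t grow = (R_xlen_t)nx * (iy + (R_xlen_t)(ny - 1) * iz);
      for (int ix = 0; ix < nx; ++ix) {
        double g = gy[grow + ix];
        y[row + ix] -= g * x[row + ix + nx];
        y[row + ix + nx] -= g * x[row + ix];
      }
    }
  }
  const R_xlen_t slab = (R_xlen_t)nx * ny;
  for (int iz = 0; iz < nz - 1; ++iz) {
    for (int iy = 0; iy < ny; ++iy) {
      R_xlen_t row = (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
      for (int ix = 0; ix < nx; ++ix) {
        double g = gz[row + ix];
        y[row + ix] -= g * x[row + ix + slab];
        y[row + ix + slab] -= g * x[row + ix];
      }
    }
  }
  for (R_xlen_t i = 0; i < n; ++i)
    if (fixed[i]) y[i] = 0.0;
}

// Jacobi-preconditioned conjugate gradients for the stencil system.
// Returns the solution on free voxels (zero at fixed), the iteration count
// and the final relative residual.
// [[Rcpp::export]]
List pcg_stencil(IntegerVector dims, NumericVector gx, NumericVector gy,
                 NumericVector gz, NumericVector diag, IntegerVector fixed,
                 NumericVector b, NumericVector x0, double tol, int maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (b.size() != n || diag.size() != n || fixed.size() != n || x0.size() != n)
    stop("inconsistent array sizes");

  NumericVector x = clone(x0);
  std::vector<double> r(n), z(n), p(n), Ap(n);
  std::vector<double> minv(n);
  const double *dg = REAL(diag);
  const int *fx = INTEGER(fixed);
  for (R_xlen_t i = 0; i < n; ++i)
    minv[i] = (!fx[i] && dg[i] > 0.0) ? 1.0 / dg[i] : 0.0;

  double bnorm = 0.0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (!fx[i]) bnorm += b[i] * b[i];
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0)
    return List::create(_["x"] = NumericVector(n), _["iterations"] = 0,
                        _["relres"] = 0.0);

  stencil_apply(nx, ny, nz, REAL(gx), REAL(gy), REAL(gz), dg, fx, REAL(x),
                Ap.data());
  for (R_xlen_t i = 0; i < n; ++i) r[i] = fx[i] ? 0.0 : b[i] - Ap[i];

  double rz = 0.0, rnorm = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    z[i] = minv[i] * r[i];
    rz += r[i] * z[i];
    rnorm += r[i] * r[i];
  }
  std::copy(z.begin(), z.end(), p.begin());

  int iter = 0;
  double relres = std::sqrt(rnorm) / bnorm;
  while (relres > tol && iter < maxit) {
    stencil_apply(nx, ny, nz, REAL(gx), REAL(gy), REAL(gz), dg, fx, p.data(),
                  Ap.data());
    double pAp = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) pAp += p[i] * Ap[i];
    if (pAp <= 0.0) break;  // numerically singular direction
    double alpha = rz / pAp;
    rnorm = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * Ap[i];
      rnorm += r[i] * r[i];
    }
    double rz_new = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      z[i] = minv[i] * r[i];
      rz_new += r[i] * z[i];
    }
    double beta = rz_new / rz;
    rz = rz_new;
    for (R_xlen_t i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
    ++iter;
    relres = std::sqrt(rnorm) / bnorm;
    if (iter % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["x"] = x, _["iterations"] = iter,
                      _["relres"] = relres);
}
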