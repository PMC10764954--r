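#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Voxel-driven FDK backprojection on the virtual detector at the isocenter.
// q: filtered (and redundancy-weighted) projections, dim (nu, nv, nviews),
// sampled at virtual-detector coordinates u'_i = u0 + i*du, v'_j = v0 + j*dv
// (dv may be negative when detector rows extend toward -z).
// Accumulates  dbeta * d_so^2 / U^2 * q(u'(r), v'(r))  per view with bilinear
// detector interpolation; rays falling off the detector contribute zero.
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector q, IntegerVector qdims,
                              NumericVector angles, double d_so,
                              double u0, double du, double v0, double dv,
                              IntegerVector dims, NumericVector origin,
                              double vpitch, double dbeta) {
  const int nu = qdims[0], nv = qdims[1], nb = qdims[2];
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(Dimension(nx, ny, nz));
  double *f = REAL(out);
  const double *qq = REAL(q);

  std::vector<double> xs(nx), ys(ny), zs(nz);
  for (int i = 0; i < nx; ++i) xs[i] = origin[0] + i * vpitch;
  for (int j = 0; j < ny; ++j) ys[j] = origin[1] + j * vpitch;
  for (int k = 0; k < nz; ++k) zs[k] = origin[2] + k * vpitch;

  for (int ib = 0; ib < nb; ++ib) {
    const double cb = std::cos(angles[ib]), sb = std::sin(angles[ib]);
    const double *qv = qq + (size_t)nu * nv * ib;
    for (int k = 0; k < nz; ++k) {
      const double z = zs[k];
      for (int j = 0; j < ny; ++j) {
        const double y = ys[j];
        double *fr = f + (size_t)nx * (j + (size_t)ny * k);
        for (int i = 0; i < nx; ++i) {
          const double x = xs[i];
          const double U = d_so - x * cb - y * sb;
          if (U < 1e-6) continue;
          const double up = d_so * (x * sb - y * cb) / U;
          const double vp = d_so * z / U;
          const double gu = (up - u0) / du;
          const double gv = (vp - v0) / dv;
          if (gu <= 0.0 || gu >= nu - 1 || gv <= 0.0 || gv >= nv - 1) continue;
          const int iu = (int)gu, iv = (int)gv;
          const double fu = gu - iu, fv = gv - iv;
          const double q00 = qv[iu + (size_t)nu * iv];
          const double q10 = qv[iu + 1 + (size_t)nu * iv];
          const double q01 = qv[iu + (size_t)nu * (iv + 1)];
          const double q11 = qv[iu + 1 + (size_t)nu * (iv + 1)];
          const double val = (1 - fu) * (1 - fv) * q00 + fu * (1 - fv) * q10 +
                             (1 - fu) * fv * q01 + fu * fv * q11;
          fr[i] += dbeta * d_so * d_so / (U * U) * val;
        }
      }
    }
  }
  return out;
}
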