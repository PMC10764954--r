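#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Clip the parametric ray s + t (d - s), t in [0, 1], to a cylindrical field
// of view (axis = z, radius R) intersected with the slab z in [z0, z1].
// Returns (t_entry, t_exit); a miss yields t_entry == t_exit.
static inline void clip_ray(const double *s, const double *d,
                            double R, double z0, double z1,
                            double &t0, double &t1) {
  t0 = 0.0; t1 = 1.0;
  const double ex = d[0] - s[0], ey = d[1] - s[1], ez = d[2] - s[2];
  const double a = ex * ex + ey * ey;
  const double b = 2.0 * (s[0] * ex + s[1] * ey);
  const double c = s[0] * s[0] + s[1] * s[1] - R * R;
  if (a < 1e-300) {
    if (c > 0.0) { t0 = t1 = 0.0; return; }
  } else {
    const double disc = b * b - 4.0 * a * c;
    if (disc <= 0.0) { t0 = t1 = 0.0; return; }
    const double sq = std::sqrt(disc);
    double r0 = (-b - sq) / (2.0 * a);
    double r1 = (-b + sq) / (2.0 * a);
    if (r0 > t0) t0 = r0;
    if (r1 < t1) t1 = r1;
  }
  // slab in z
  if (std::abs(ez) < 1e-300) {
    if (s[2] < z0 || s[2] > z1) { t0 = t1 = 0.0; return; }
  } else {
    double r0 = (z0 - s[2]) / ez;
    double r1 = (z1 - s[2]) / ez;
    if (r0 > r1) std::swap(r0, r1);
    if (r0 > t0) t0 = r0;
    if (r1 < t1) t1 = r1;
  }
  if (t1 <= t0) { t0 = t1 = 0.0; }
}

// [[Rcpp::export]]
NumericVector cpp_clip_ray(NumericVector src, NumericVector det,
                           double fov_radius, double z0, double z1) {
  double t0, t1;
  clip_ray(REAL(src), REAL(det), fov_radius, z0, z1, t0, t1);
  return NumericVector::create(t0, t1);
}

// Trilinear interpolation of a volume sampled at voxel centers; zero outside.
// origin = world position of the center of voxel (0,0,0); isotropic pitch.
static inline double trilinear(const double *vol, int nx, int ny, int nz,
                               double ox, double oy, double oz, double pitch,
                               double x, double y, double z) {
  const double gx = (x - ox) / pitch;
  const double gy = (y - oy) / pitch;
  const double gz = (z - oz) / pitch;
  if (gx <= -1.0 || gy <= -1.0 || gz <= -1.0 ||
      gx >= nx || gy >= ny || gz >= nz) return 0.0;
  int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy), k0 = (int)std::floor(gz);
  const double fx = gx - i0, fy = gy - j0, fz = gz - k0;
  double acc = 0.0;
  for (int dk = 0; dk < 2; ++dk) {
    const int k = k0 + dk;
    if (k < 0 || k >= nz) continue;
    const double wz = dk ? fz : 1.0 - fz;
    for (int dj = 0; dj < 2; ++dj) {
      const int j = j0 + dj;
      if (j < 0 || j >= ny) continue;
      const double wy = dj ? fy : 1.0 - fy;
      for (int di = 0; di < 2; ++di) {
        const int i = i0 + di;
        if (i < 0 || i >= nx) continue;
        const double wx = di ? fx : 1.0 - fx;
        acc += wx * wy * wz * vol[i + (size_t)nx * (j + (size_t)ny * k)];
      }
    }
  }
  return acc;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dims,
                            NumericVector origin, double pitch,
                            NumericMatrix pts) {
  const int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = trilinear(REAL(vol), dims[0], dims[1], dims[2],
                       origin[0], origin[1], origin[2], pitch,
                       pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

// Deterministic cone-beam forward projector: midpoint rule on uniform bins
// along each FOV-clipped ray; segment lengths converted mm -> cm so the
// result is consistent with attenuation in 1/cm.
// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector vol, IntegerVector dims,
                                  NumericVector origin, double vpitch,
                                  NumericVector angles, double d_so, double d_sd,
                                  NumericVector xu, NumericVector zv,
                                  double fov_radius, NumericVector fov_z,
                                  int nsamp) {
  const int nu = xu.size(), nv = zv.size(), nb = angles.size();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  NumericVector out(Dimension(nu, nv, nb));
  const double *v = REAL(vol);
  double *o = REAL(out);
  for (int ib = 0; ib < nb; ++ib) {
    const double cb = std::cos(angles[ib]), sb = std::sin(angles[ib]);
    const double s[3] = { d_so * cb, d_so * sb, 0.0 };
    const double cx = (d_so - d_sd) * cb, cy = (d_so - d_sd) * sb;
    const double eux = sb, euy = -cb;
    for (int iv = 0; iv < nv; ++iv) {
      const double dz = zv[iv];
      for (int iu = 0; iu < nu; ++iu) {
        const double d[3] = { cx + xu[iu] * eux, cy + xu[iu] * euy, dz };
        double t0, t1;
        clip_ray(s, d, fov_radius, fov_z[0], fov_z[1], t0, t1);
        double p = 0.0;
        if (t1 > t0) {
          const double ex = d[0] - s[0], ey = d[1] - s[1], ez = d[2] - s[2];
          const double rl = std::sqrt(ex * ex + ey * ey + ez * ez);
          const double dt = (t1 - t0) / nsamp;
          double acc = 0.0;
          for (int k = 0; k < nsamp; ++k) {
            const double t = t0 + (k + 0.5) * dt;
            acc += trilinear(v, nx, ny, nz, ox, oy, oz, vpitch,
                             s[0] + t * ex, s[1] + t * ey, s[2] + t * ez);
          }
          p = acc * dt * rl * 0.1;  // mm -> cm
        }
        o[iu + (size_t)nu * (iv + (size_t)nv * ib)] = p;
      }
    }
  }
  return out;
}
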