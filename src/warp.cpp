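#include <Rcpp.h>
#include "geom.h"
using namespace Rcpp;

// Combined rotate + warp in a single trilinear pass.  The output grid is
// detector-aligned: (iu, iv, id) with detector pixel pitch `pitch` (mm) and
// depth planes at d = (id + 0.5) * pitch from the collimator face.  The
// region is one affine axis map per detector axis: u = ex + (x - ex) * Mx(d),
// Mx = Fx/(Fx - d) (signed F; ~1e12 means parallel).
//
// vol: column-major (nx, ny, nz), voxel size vox (mm, isotropic), origin =
// world mm of the centre of voxel [1,1,1].

// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector vol, IntegerVector dim, double vox,
                       NumericVector origin, NumericVector center,
                       double phi, double Rad,
                       double Fx, double ex, double Fy, double ey,
                       int nu, int nv, int nd, double pitch) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  ViewFrame f = make_view(phi, Rad, center[0], center[1], center[2]);
  NumericVector out(static_cast<R_xlen_t>(nu) * nv * nd);
  out.attr("dim") = IntegerVector::create(nu, nv, nd);
  const double* v = REAL(vol);
  double* o = REAL(out);
  double u0 = -0.5 * (nu - 1) * pitch, v0 = -0.5 * (nv - 1) * pitch;
  for (int id = 0; id < nd; ++id) {
    double d = (id + 0.5) * pitch;
    if (Fx > 0 && d >= FOCAL_CUT * Fx) continue;
    if (Fy > 0 && d >= FOCAL_CUT * Fy) continue;
    double Mx = Fx / (Fx - d), My = Fy / (Fy - d);
    for (int iv = 0; iv < nv; ++iv) {
      double ya = ey + (v0 + iv * pitch - ey) / My;
      for (int iu = 0; iu < nu; ++iu) {
        double xt = ex + (u0 + iu * pitch - ex) / Mx;
        double px, py, pz;
        view_to_world(f, xt, ya, d, px, py, pz);
        double gx = (px - origin[0]) / vox;
        double gy = (py - origin[1]) / vox;
        double gz = (pz - origin[2]) / vox;
        o[iu + (size_t)nu * (iv + (size_t)nv * id)] =
            trilinear(v, nx, ny, nz, gx, gy, gz);
      }
    }
  }
  return out;
}

// Exact transpose of cpp_warp (splat with identical weights).

// [[Rcpp::export]]
NumericVector cpp_warp_adjoint(NumericVector warped, IntegerVector dim,
                               double vox, NumericVector origin,
                               NumericVector center, double phi, double Rad,
                               double Fx, double ex, double Fy, double ey,
                               int nu, int nv, int nd, double pitch) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  ViewFrame f = make_view(phi, Rad, center[0], center[1], center[2]);
  NumericVector out(static_cast<R_xlen_t>(nx) * ny * nz);
  out.attr("dim") = dim;
  const double* w = REAL(warped);
  double* o = REAL(out);
  double u0 = -0.5 * (nu - 1) * pitch, v0 = -0.5 * (nv - 1) * pitch;
  for (int id = 0; id < nd; ++id) {
    double d = (id + 0.5) * pitch;
    if (Fx > 0 && d >= FOCAL_CUT * Fx) continue;
    if (Fy > 0 && d >= FOCAL_CUT * Fy) continue;
    double Mx = Fx / (Fx - d), My = Fy / (Fy - d);
    for (int iv = 0; iv < nv; ++iv) {
      double ya = ey + (v0 + iv * pitch - ey) / My;
      for (int iu = 0; iu < nu; ++iu) {
        double val = w[iu + (size_t)nu * (iv + (size_t)nv * id)];
        if (val == 0) continue;
        double xt = ex + (u0 + iu * pitch - ex) / Mx;
        double px, py, pz;
        view_to_world(f, xt, ya, d, px, py, pz);
        double gx = (px - origin[0]) / vox;
        double gy = (py - origin[1]) / vox;
        double gz = (pz - origin[2]) / vox;
        trilinear_splat(o, nx, ny, nz, gx, gy, gz, val);
      }
    }
  }
  return out;
}

// Depth-cumulative attenuation in the warped frame.  mu_w holds linear
// attenuation (per cm) resampled onto the detector-aligned grid; sec is the
// per-pixel secant of the hole inclination (path length per unit depth).
// Returns T(iu,iv,id) = exp(-sec * integral of mu from the voxel to the
// face), midpoint rule.

// [[Rcpp::export]]
NumericVector cpp_cumatt(NumericVector mu_w, NumericVector sec, double pitch) {
  IntegerVector dim = mu_w.attr("dim");
  int nu = dim[0], nv = dim[1], nd = dim[2];
  NumericVector out(mu_w.size());
  out.attr("dim") = dim;
  const double* m = REAL(mu_w);
  const double* s = REAL(sec);
  double* o = REAL(out);
  double step_cm = 0.1 * pitch;
  for (int iv = 0; iv < nv; ++iv)
    for (int iu = 0; iu < nu; ++iu) {
      double acc = 0.0;
      double sc = s[iu + (size_t)nu * iv] * step_cm;
      for (int id = 0; id < nd; ++id) {
        size_t ix = iu + (size_t)nu * (iv + (size_t)nv * id);
        double half = 0.5 * m[ix];
        o[ix] = std::exp(-(acc + half) * sc);
        acc += m[ix];
      }
    }
  return out;
}

// Geometric point-sensitivity map: view-averaged J * |Mx * My| for the zone
// that sees each voxel (0 when unseen), i.e. the relative point-source
// sensitivity of the collimator across the volume.

// [[Rcpp::export]]
NumericVector cpp_sens_map(IntegerVector dim, double vox,
                           NumericVector origin, NumericVector center,
                           NumericVector phis, NumericVector Rads,
                           NumericMatrix zx, NumericMatrix zy) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nviews = phis.size();
  NumericVector out(static_cast<R_xlen_t>(nx) * ny * nz);
  out.attr("dim") = dim;
  double* o = REAL(out);
  for (int vi = 0; vi < nviews; ++vi) {
    ViewFrame f = make_view(phis[vi], Rads[vi], center[0], center[1],
                            center[2]);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          double px = origin[0] + i * vox;
          double py = origin[1] + j * vox;
          double pz = origin[2] + k * vox;
          double xt, ya, d;
          world_to_view(f, px, py, pz, xt, ya, d);
          if (d <= 0) continue;
          double u, su, Mu, v, sv, Mv;
          if (!axis_obj2det(zx, xt, d, u, su, Mu)) continue;
          if (!axis_obj2det(zy, ya, d, v, sv, Mv)) continue;
          double Fx, ex, Fy, ey;
          if (!axis_zone_at(zx, u, Fx, ex) || !axis_zone_at(zy, v, Fy, ey))
            continue;
          double J = 1 + su * su + sv * sv;
          double Mx = Fx / (Fx - d), My = Fy / (Fy - d);
          o[i + (size_t)nx * (j + (size_t)ny * k)] +=
              J * std::fabs(Mx * My);
        }
  }
  for (R_xlen_t t = 0; t < out.size(); ++t) o[t] /= nviews;
  return out;
}

// Fraction of views in which each voxel projects inside the crystal.
// zx, zy: axis zone matrices; half-widths of the crystal are implied by the
// zone extents.

// [[Rcpp::export]]
NumericVector cpp_fov_fraction(IntegerVector dim, double vox,
                               NumericVector origin, NumericVector center,
                               NumericVector phis, NumericVector Rads,
                               NumericMatrix zx, NumericMatrix zy) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nviews = phis.size();
  NumericVector out(static_cast<R_xlen_t>(nx) * ny * nz);
  out.attr("dim") = dim;
  double* o = REAL(out);
  for (int vi = 0; vi < nviews; ++vi) {
    ViewFrame f = make_view(phis[vi], Rads[vi], center[0], center[1],
                            center[2]);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          double px = origin[0] + i * vox;
          double py = origin[1] + j * vox;
          double pz = origin[2] + k * vox;
          double xt, ya, d;
          world_to_view(f, px, py, pz, xt, ya, d);
          if (d <= 0) continue;
          double u, su, Mu, v, sv, Mv;
          if (axis_obj2det(zx, xt, d, u, su, Mu) &&
              axis_obj2det(zy, ya, d, v, sv, Mv))
            o[i + (size_t)nx * (j + (size_t)ny * k)] += 1.0;
        }
  }
  for (R_xlen_t t = 0; t < out.size(); ++t) o[t] /= nviews;
  return out;
}
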