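#pragma once
#include <Rcpp.h>
#include <cmath>

// View frame: detector normal n = (cos phi, sin phi, 0) points from the
// rotation center toward the detector; e_u = (-sin phi, cos phi, 0) spans the
// transaxial detector axis, e_v = +z the axial axis.  Depth d is measured from
// the collimator face into the patient, so the face plane sits at distance
// Rad from the rotation center.
struct ViewFrame {
  double nx, ny;
  double ux, uy;
  double cx, cy, cz, Rad;
};

inline ViewFrame make_view(double phi, double Rad,
                           double cx, double cy, double cz) {
  ViewFrame f;
  f.nx = std::cos(phi); f.ny = std::sin(phi);
  f.ux = -std::sin(phi); f.uy = std::cos(phi);
  f.cx = cx; f.cy = cy; f.cz = cz; f.Rad = Rad;
  return f;
}

inline void world_to_view(const ViewFrame& f, double px, double py, double pz,
                          double& xt, double& ya, double& d) {
  double rx = px - f.cx, ry = py - f.cy, rz = pz - f.cz;
  xt = rx * f.ux + ry * f.uy;
  ya = rz;
  d  = f.Rad - (rx * f.nx + ry * f.ny);
}

inline void view_to_world(const ViewFrame& f, double xt, double ya, double d,
                          double& px, double& py, double& pz) {
  double a = f.Rad - d;
  px = f.cx + a * f.nx + xt * f.ux;
  py = f.cy + a * f.ny + xt * f.uy;
  pz = f.cz + ya;
}

// One collimator axis is a set of zones on the detector, each an affine map
// u = e + (x - e) * F/(F - d) between object transverse coordinate x at depth
// d and detector coordinate u.  F > 0: converging focal length; F < 0:
// diverging (|F| behind the detector); F ~ 1e12 encodes parallel holes.
// Zone matrix columns: lo, hi (detector mm), F (mm), e (mm).

// Converging zones stop resolving just short of the focal plane; content at
// or beyond the focal point is treated as unseen by that zone.
const double FOCAL_CUT = 0.95;

inline bool axis_obj2det(const Rcpp::NumericMatrix& zn, double x, double d,
                         double& u, double& s, double& M) {
  for (int i = 0; i < zn.nrow(); ++i) {
    double F = zn(i, 2), e = zn(i, 3);
    if (F > 0 && d >= FOCAL_CUT * F) continue;
    double Mz = F / (F - d);
    double uu = e + (x - e) * Mz;
    if (uu >= zn(i, 0) - 1e-9 && uu <= zn(i, 1) + 1e-9) {
      u = uu;
      s = (uu - e) / F;
      M = Mz;
      return true;
    }
  }
  return false;
}

inline bool axis_zone_at(const Rcpp::NumericMatrix& zn, double u,
                         double& F, double& e) {
  for (int i = 0; i < zn.nrow(); ++i)
    if (u >= zn(i, 0) - 1e-9 && u <= zn(i, 1) + 1e-9) {
      F = zn(i, 2); e = zn(i, 3);
      return true;
    }
  return false;
}

// trilinear gather from a column-major (nx,ny,nz) array; grid coordinates in
// voxel units of the voxel centres (0-based); zero outside.
inline double trilinear(const double* v, int nx, int ny, int nz,
                        double gx, double gy, double gz) {
  int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy),
      k0 = (int)std::floor(gz);
  double fx = gx - i0, fy = gy - j0, fz = gz - k0;
  double out = 0.0;
  for (int dk = 0; dk < 2; ++dk) {
    int k = k0 + dk;
    if (k < 0 || k >= nz) continue;
    double wz = dk ? fz : 1 - fz;
    for (int dj = 0; dj < 2; ++dj) {
      int j = j0 + dj;
      if (j < 0 || j >= ny) continue;
      double wy = dj ? fy : 1 - fy;
      for (int di = 0; di < 2; ++di) {
        int i = i0 + di;
        if (i < 0 || i >= nx) continue;
        double wx = di ? fx : 1 - fx;
        out += wx * wy * wz * v[i + (size_t)nx * (j + (size_t)ny * k)];
      }
    }
  }
  return out;
}

inline void trilinear_splat(double* v, int nx, int ny, int nz,
                            double gx, double gy, double gz, double val) {
  int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy),
      k0 = (int)std::floor(gz);
  double fx = gx - i0, fy = gy - j0, fz = gz - k0;
  for (int dk = 0; dk < 2; ++dk) {
    int k = k0 + dk;
    if (k < 0 || k >= nz) continue;
    double wz = dk ? fz : 1 - fz;
    for (int dj = 0; dj < 2; ++dj) {
      int j = j0 + dj;
      if (j < 0 || j >= ny) continue;
      double wy = dj ? fy : 1 - fy;
      for (int di = 0; di < 2; ++di) {
        int i = i0 + di;
        if (i < 0 || i >= nx) continue;
        double wx = di ? fx : 1 - fx;
        v[i + (size_t)nx * (j + (size_t)ny * k)] += wx * wy * wz * val;
      }
    }
  }
}
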