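#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Exact voxel ray traversal (Siddon-type): integral of the volume values
// along the segment p0 -> p1.  Volume values are interpreted as a density of
// "value per cm"; the returned integral uses path lengths in cm.
// Voxel [i,j,k] (0-based) spans origin + (i - 0.5, i + 0.5) * vox etc.,
// where origin is the world position of the centre of voxel [1,1,1].

// [[Rcpp::export]]
double cpp_siddon(NumericVector vol, IntegerVector dim, double vox,
                  NumericVector origin, NumericVector p0, NumericVector p1) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = REAL(vol);
  double d0[3] = {p0[0], p0[1], p0[2]};
  double d1[3] = {p1[0], p1[1], p1[2]};
  double dir[3] = {d1[0] - d0[0], d1[1] - d0[1], d1[2] - d0[2]};
  double L = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] + dir[2] * dir[2]);
  if (L < 1e-12) return 0.0;
  // grid bounds (faces of the outermost voxels), world mm
  double lo[3], hi[3];
  int n[3] = {nx, ny, nz};
  for (int a = 0; a < 3; ++a) {
    lo[a] = origin[a] - 0.5 * vox;
    hi[a] = origin[a] + (n[a] - 0.5) * vox;
  }
  // clip segment to grid: parametric t in [0,1]
  double tmin = 0.0, tmax = 1.0;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(dir[a]) < 1e-12) {
      if (d0[a] < lo[a] || d0[a] > hi[a]) return 0.0;
    } else {
      double t1 = (lo[a] - d0[a]) / dir[a];
      double t2 = (hi[a] - d0[a]) / dir[a];
      if (t1 > t2) std::swap(t1, t2);
      tmin = std::max(tmin, t1);
      tmax = std::min(tmax, t2);
    }
  }
  if (tmin >= tmax) return 0.0;
  double integral = 0.0;
  double t = tmin;
  // current voxel at entry
  while (t < tmax - 1e-12) {
    double mid[3];
    // step to the next voxel boundary
    double tnext = tmax;
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(dir[a]) < 1e-12) continue;
      double pos = d0[a] + t * dir[a];
      double g = (pos - lo[a]) / vox;  // in [0, n]
      double bnext = dir[a] > 0 ? (std::floor(g + 1e-9) + 1.0)
                                : (std::ceil(g - 1e-9) - 1.0);
      double ta = (lo[a] + bnext * vox - d0[a]) / dir[a];
      if (ta > t + 1e-12) tnext = std::min(tnext, ta);
    }
    if (tnext <= t + 1e-12) tnext = t + 1e-9;
    double tm = 0.5 * (t + tnext);
    for (int a = 0; a < 3; ++a) mid[a] = d0[a] + tm * dir[a];
    int i = (int)std::floor((mid[0] - lo[0]) / vox);
    int j = (int)std::floor((mid[1] - lo[1]) / vox);
    int k = (int)std::floor((mid[2] - lo[2]) / vox);
    if (i >= 0 && i < nx && j >= 0 && j < ny && k >= 0 && k < nz)
      integral += v[i + (size_t)nx * (j + (size_t)ny * k)] *
                  (tnext - t) * L;
    t = tnext;
  }
  return integral * 0.1;  // mm -> cm
}
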