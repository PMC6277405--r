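#pragma once
#include <Rcpp.h>
#include <cmath>

// Voxelized medium: density grid (g/cm^3) plus a water-shaped mass
// attenuation table; all materials in the phantoms (water, lung, air) are
// modeled as water of the local density, which is accurate for the
// Compton-dominated 50-160 keV range used here.
struct Medium {
  const double* dens;  // may be nullptr (vacuum)
  int nx, ny, nz;
  double vox;          // mm
  double ox, oy, oz;   // world mm of voxel [1,1,1] centre
  // mass attenuation table, regular energy grid
  double Elo, Estep;
  const double* mr_tot;   // cm^2/g
  const double* mr_comp;  // cm^2/g
  int ntab;
  double dens_max;
};

inline double tab_interp(const Medium& m, const double* tab, double E) {
  double g = (E - m.Elo) / m.Estep;
  if (g <= 0) return tab[0];
  int i = (int)g;
  if (i >= m.ntab - 1) return tab[m.ntab - 1];
  double f = g - i;
  return tab[i] * (1 - f) + tab[i + 1] * f;
}

inline double murho_tot(const Medium& m, double E) {
  return tab_interp(m, m.mr_tot, E);
}
inline double murho_comp(const Medium& m, double E) {
  return tab_interp(m, m.mr_comp, E);
}

inline double dens_at(const Medium& m, double px, double py, double pz) {
  if (!m.dens) return 0.0;
  int i = (int)std::floor((px - m.ox) / m.vox + 0.5);
  int j = (int)std::floor((py - m.oy) / m.vox + 0.5);
  int k = (int)std::floor((pz - m.oz) / m.vox + 0.5);
  if (i < 0 || i >= m.nx || j < 0 || j >= m.ny || k < 0 || k >= m.nz)
    return 0.0;
  return m.dens[i + (size_t)m.nx * (j + (size_t)m.ny * k)];
}

// line integral of mu (per cm) from p along dir over length L_mm, fixed-step
// midpoint sampling (used for forced-detection exit attenuation)
inline double mu_line(const Medium& m, double px, double py, double pz,
                      double dx, double dy, double dz, double L_mm,
                      double E) {
  if (!m.dens || L_mm <= 0) return 0.0;
  double mr = murho_tot(m, E);
  double step = 0.7 * m.vox;
  int n = (int)(L_mm / step) + 1;
  double h = L_mm / n;
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double t = (i + 0.5) * h;
    acc += dens_at(m, px + t * dx, py + t * dy, pz + t * dz);
  }
  return acc * mr * h * 0.1;  // mm -> cm
}

// bilinear deposit on a detector plane stored column-major (nu x nv)
inline void deposit2d(double* img, int nu, int nv, double pu, double pv,
                      double val) {
  int i0 = (int)std::floor(pu), j0 = (int)std::floor(pv);
  double fx = pu - i0, fy = pv - j0;
  for (int dj = 0; dj < 2; ++dj) {
    int j = j0 + dj;
    if (j < 0 || j >= nv) continue;
    double wy = dj ? fy : 1 - fy;
    for (int di = 0; di < 2; ++di) {
      int i = i0 + di;
      if (i < 0 || i >= nu) continue;
      double wx = di ? fx : 1 - fx;
      img[i + (size_t)nu * j] += wx * wy * val;
    }
  }
}
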