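#include <Rcpp.h>
#include "geom.h"
#include "compton.h"
#include "transport.h"
using namespace Rcpp;

// Forced-detection Compton scatter projector.  Emission sites are sampled
// proportionally to activity; photons are transported by Woodcock (delta)
// tracking through the density map; at every interaction the photon is
// forced toward each detector view with a deterministic weight
//
//   w * [4pi * p_KN(theta_s)] * g * J(u,v) * exp(-int mu(E') dl) * P_win(E')
//
// and deposited at the projected detector position, binned by depth so the
// caller can apply the depth-dependent PSF.  Photoelectric absorption is
// handled by weight (survival biasing); histories are capped at
// `order_cap` scatter orders.
//
// Returns, per energy window, an array (nu, nv, ndbins, nviews) of mean
// counts per emitted decay (caller scales by activity * time).

// [[Rcpp::export]]
List cpp_mc_scatter(NumericVector cumact, IntegerVector dim, double vox,
                    NumericVector origin, NumericVector dens,
                    NumericVector center, NumericVector phis,
                    NumericVector Rads, NumericMatrix zx, NumericMatrix zy,
                    double g_sens, NumericMatrix windows, double eres140,
                    NumericVector murho_E, NumericVector murho_t,
                    NumericVector murho_c, double E0, double ecut,
                    int order_cap, int n_hist, int nu, int nv, double pitch,
                    int ndbins, double dmax, double mu_crystal,
                    double t_crystal) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nviews = phis.size(), nwin = windows.nrow();
  Medium med;
  med.dens = REAL(dens);
  med.nx = nx; med.ny = ny; med.nz = nz; med.vox = vox;
  med.ox = origin[0]; med.oy = origin[1]; med.oz = origin[2];
  med.Elo = murho_E[0]; med.Estep = murho_E[1] - murho_E[0];
  med.mr_tot = REAL(murho_t); med.mr_comp = REAL(murho_c);
  med.ntab = murho_t.size();
  med.dens_max = 0;
  for (R_xlen_t t = 0; t < dens.size(); ++t)
    med.dens_max = std::max(med.dens_max, med.dens[t]);

  std::vector<ViewFrame> views(nviews);
  for (int i = 0; i < nviews; ++i)
    views[i] = make_view(phis[i], Rads[i], center[0], center[1], center[2]);

  List out(nwin);
  std::vector<double*> imgs(nwin);
  for (int w = 0; w < nwin; ++w) {
    NumericVector a(static_cast<R_xlen_t>(nu) * nv * ndbins * nviews);
    a.attr("dim") = IntegerVector::create(nu, nv, ndbins, nviews);
    out[w] = a;
    imgs[w] = REAL(a);
  }
  const double* ca = REAL(cumact);
  double atot = ca[cumact.size() - 1];
  double u_half = 0.5 * (nu - 1), v_half = 0.5 * (nv - 1);
  // grid bbox for escape test
  double blo[3] = {med.ox - 0.5 * vox, med.oy - 0.5 * vox, med.oz - 0.5 * vox};
  double bhi[3] = {med.ox + (nx - 0.5) * vox, med.oy + (ny - 0.5) * vox,
                   med.oz + (nz - 0.5) * vox};

  for (int h = 0; h < n_hist; ++h) {
    // emission site: activity-weighted voxel, uniform inside
    double r = unif_rand() * atot;
    R_xlen_t lo = 0, hi = cumact.size() - 1;
    while (lo < hi) {
      R_xlen_t mid = (lo + hi) / 2;
      if (ca[mid] < r) lo = mid + 1; else hi = mid;
    }
    int i = lo % nx, j = (lo / nx) % ny, k = lo / ((R_xlen_t)nx * ny);
    double px = med.ox + (i + unif_rand() - 0.5) * vox;
    double py = med.oy + (j + unif_rand() - 0.5) * vox;
    double pz = med.oz + (k + unif_rand() - 0.5) * vox;
    double cth = 2 * unif_rand() - 1;
    double phi0 = 2 * M_PI * unif_rand();
    double sth = std::sqrt(1 - cth * cth);
    double dx = sth * std::cos(phi0), dy = sth * std::sin(phi0), dz = cth;
    double E = E0, w = 1.0;
    for (int order = 1; order <= order_cap; ++order) {
      // Woodcock flight to the next real interaction
      double mumax = med.dens_max * murho_tot(med, E);  // per cm
      bool interacted = false;
      for (;;) {
        double s = -std::log(unif_rand()) / mumax * 10.0;  // mm
        px += s * dx; py += s * dy; pz += s * dz;
        if (px < blo[0] || px > bhi[0] || py < blo[1] || py > bhi[1] ||
            pz < blo[2] || pz > bhi[2])
          break;  // escaped the phantom grid
        double mu = dens_at(med, px, py, pz) * murho_tot(med, E);
        if (unif_rand() < mu / mumax) { interacted = true; break; }
      }
      if (!interacted) break;
      w *= murho_comp(med, E) / murho_tot(med, E);  // force Compton
      // forced detection toward every view
      for (int vi = 0; vi < nviews; ++vi) {
        const ViewFrame& f = views[vi];
        double xt, ya, dpt;
        world_to_view(f, px, py, pz, xt, ya, dpt);
        if (dpt <= 1e-6) continue;
        double u, sx, Mx, v, sy, My;
        if (!axis_obj2det(zx, xt, dpt, u, sx, Mx)) continue;
        if (!axis_obj2det(zy, ya, dpt, v, sy, My)) continue;
        double sec = std::sqrt(1 + sx * sx + sy * sy);
        // exit direction (unit, world)
        double exn = 1.0 / sec;
        double exu = sx / sec, exv = sy / sec;
        double wx = exu * f.ux + exn * f.nx;
        double wy = exu * f.uy + exn * f.ny;
        double wz = exv;
        double costs = dx * wx + dy * wy + dz * wz;
        double Ep = compton_eprime(E, costs);
        if (Ep < ecut) continue;
        double kn = kn_w4pi(E, costs);
        double L = dpt * sec;  // mm to the collimator face
        double T = std::exp(-mu_line(med, px, py, pz, wx, wy, wz, L, Ep));
        double J = sec * sec;
        double p_det = 1.0 - std::exp(-mu_crystal * 0.1 * t_crystal * sec);
        // acceptance integral from an interior point carries the region's
        // magnification area factor on top of g * J
        double base = w * kn * g_sens * J * std::fabs(Mx * My) * T * p_det;
        int db = (int)(dpt / dmax * ndbins);
        if (db < 0) db = 0;
        if (db >= ndbins) db = ndbins - 1;
        double pu = u / pitch + u_half, pv = v / pitch + v_half;
        for (int wi = 0; wi < nwin; ++wi) {
          double pw = window_prob(Ep, windows(wi, 0), windows(wi, 1), eres140);
          if (pw < 1e-12) continue;
          deposit2d(imgs[wi] + (size_t)nu * nv * (db + (size_t)ndbins * vi),
                    nu, nv, pu, pv, base * pw);
        }
      }
      // analog continuation
      double c = kn_sample_cost(E);
      E = compton_eprime(E, c);
      if (E < ecut) break;
      rotate_dir(dx, dy, dz, c);
    }
  }
  for (int wi = 0; wi < nwin; ++wi) {
    NumericVector a = out[wi];
    double* p = REAL(a);
    for (R_xlen_t t = 0; t < a.size(); ++t) p[t] /= n_hist;
  }
  return out;
}
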