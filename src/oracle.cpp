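#include <Rcpp.h>
#include "geom.h"
#include "compton.h"
#include "transport.h"
using namespace Rcpp;

// Brute-force Monte Carlo oracle projector for a single view.
//
// Photons are emitted from a point source or activity-weighted voxels and
// tracked analogically (Woodcock) through the density grid.  At the
// collimator face the photon is accepted through the hole array with a
// statistical model: the local hole axis follows the focusing geometry and
// the transmission probability is the circular-bore overlap at the photon's
// angular deviation from that axis (times the open-area fraction), using
// the septal-penetration-corrected hole length.  Each crossing carries the
// 1/cos^2(theta) spherical-capture-to-flat-detector Jacobian -- the same
// law the fast projector applies per pixel -- and the crystal stopping
// power and mean interaction depth depend on the incidence angle, which
// shifts and skews the detected position (the angled-crystal effect).
//
// Emission modes: 0 = isotropic, all orders; 1 = cone importance sampling
// toward the detector, primaries only (history killed at first interaction);
// 2 = isotropic, scattered photons only.  Cone sampling changes only the
// emission direction density (exact solid-angle weight); transport stays
// analog.
//
// Returns per-window weight images, squared-weight images (for MC standard
// errors) and the accepted count.

static double circle_overlap(double x) {
  if (x >= 1.0) return 0.0;
  return (2.0 / M_PI) * (std::acos(x) - x * std::sqrt(1.0 - x * x));
}

// [[Rcpp::export]]
List cpp_mc_oracle(NumericVector src_point, NumericVector cumact,
                   IntegerVector dim, double vox, NumericVector origin,
                   NumericVector dens, NumericVector center, double phi,
                   double Rad, NumericMatrix zx, NumericMatrix zy,
                   double hole_d, double L_eff, double f_open,
                   double mu_crystal, double t_crystal,
                   NumericMatrix windows, double eres140,
                   NumericVector murho_E, NumericVector murho_t,
                   NumericVector murho_c, double E0, double ecut,
                   int order_cap, int mode, int n_hist, int nu, int nv,
                   double pitch) {
  int nwin = windows.nrow();
  bool point_mode = src_point.size() == 3;
  bool vacuum = dens.size() == 0;
  Medium med;
  med.dens = vacuum ? nullptr : REAL(dens);
  med.nx = dim[0]; med.ny = dim[1]; med.nz = dim[2]; med.vox = vox;
  med.ox = origin[0]; med.oy = origin[1]; med.oz = origin[2];
  med.Elo = murho_E[0]; med.Estep = murho_E[1] - murho_E[0];
  med.mr_tot = REAL(murho_t); med.mr_comp = REAL(murho_c);
  med.ntab = murho_t.size();
  med.dens_max = 0;
  if (!vacuum)
    for (R_xlen_t t = 0; t < dens.size(); ++t)
      med.dens_max = std::max(med.dens_max, med.dens[t]);

  ViewFrame f = make_view(phi, Rad, center[0], center[1], center[2]);
  List imgs(nwin), imgs2(nwin);
  std::vector<double*> pi_(nwin), pi2_(nwin);
  for (int w = 0; w < nwin; ++w) {
    NumericMatrix a(nu, nv), b(nu, nv);
    imgs[w] = a; imgs2[w] = b;
    pi_[w] = REAL(a); pi2_[w] = REAL(b);
  }
  const double* ca = point_mode ? nullptr : REAL(cumact);
  double atot = point_mode ? 1.0 : ca[cumact.size() - 1];
  double u_half = 0.5 * (nu - 1), v_half = 0.5 * (nv - 1);
  double blo[3] = {med.ox - 0.5 * vox, med.oy - 0.5 * vox, med.oz - 0.5 * vox};
  double bhi[3] = {med.ox + (med.nx - 0.5) * vox,
                   med.oy + (med.ny - 0.5) * vox,
                   med.oz + (med.nz - 0.5) * vox};
  double crystal_ulo = zx(0, 0), crystal_uhi = zx(zx.nrow() - 1, 1);
  double crystal_vlo = zy(0, 0), crystal_vhi = zy(zy.nrow() - 1, 1);
  long n_acc = 0;

  for (int h = 0; h < n_hist; ++h) {
    double px, py, pz;
    if (point_mode) {
      px = src_point[0]; py = src_point[1]; pz = src_point[2];
    } else {
      double r = unif_rand() * atot;
      R_xlen_t lo = 0, hi = cumact.size() - 1;
      while (lo < hi) {
        R_xlen_t mid = (lo + hi) / 2;
        if (ca[mid] < r) lo = mid + 1; else hi = mid;
      }
      int i = lo % med.nx, j = (lo / med.nx) % med.ny,
          k = lo / ((R_xlen_t)med.nx * med.ny);
      px = med.ox + (i + unif_rand() - 0.5) * vox;
      py = med.oy + (j + unif_rand() - 0.5) * vox;
      pz = med.oz + (k + unif_rand() - 0.5) * vox;
    }
    double w = 1.0, dx, dy, dz;
    if (mode == 1) {
      // cone importance sampling about the local accepted direction
      double xt, ya, dpt, u, sx, Mx_, v, sy, My_;
      world_to_view(f, px, py, pz, xt, ya, dpt);
      bool ok = dpt > 1e-6 && axis_obj2det(zx, xt, dpt, u, sx, Mx_) &&
                axis_obj2det(zy, ya, dpt, v, sy, My_);
      if (ok) {
        double sec = std::sqrt(1 + sx * sx + sy * sy);
        double ax = (sx / sec) * f.ux + (1 / sec) * f.nx;
        double ay = (sx / sec) * f.uy + (1 / sec) * f.ny;
        double az = sy / sec;
        double Fx, ex, Fy, ey, Mm = 1.0;
        if (axis_zone_at(zx, u, Fx, ex)) Mm = std::fabs(Fx / (Fx - dpt));
        if (axis_zone_at(zy, v, Fy, ey))
          Mm = std::max(Mm, std::fabs(Fy / (Fy - dpt)));
        double dmaxang =
            std::min(0.5, 2.0 * Mm * std::atan(hole_d / L_eff));
        double cmin = std::cos(dmaxang);
        w = 0.5 * (1.0 - cmin);
        double c = cmin + unif_rand() * (1.0 - cmin);
        dx = ax; dy = ay; dz = az;
        rotate_dir(dx, dy, dz, c);
      } else {
        // no accepted direction from here: emit isotropically (rare)
        double cth = 2 * unif_rand() - 1, ph = 2 * M_PI * unif_rand();
        double sth = std::sqrt(1 - cth * cth);
        dx = sth * std::cos(ph); dy = sth * std::sin(ph); dz = cth;
      }
    } else {
      double cth = 2 * unif_rand() - 1, ph = 2 * M_PI * unif_rand();
      double sth = std::sqrt(1 - cth * cth);
      dx = sth * std::cos(ph); dy = sth * std::sin(ph); dz = cth;
    }
    double E = E0;
    int order = 0;
    bool alive = true;
    while (alive) {
      // distance to the collimator face plane along the current direction
      double dirn = dx * f.nx + dy * f.ny;  // depth decreases at rate dirn
      double xt0, ya0, dpt0;
      world_to_view(f, px, py, pz, xt0, ya0, dpt0);
      double s_face = dirn > 1e-9 ? dpt0 / dirn : R_PosInf;
      double s_int = R_PosInf;
      if (!vacuum && med.dens_max > 0) {
        double mumax = med.dens_max * murho_tot(med, E);
        double trav = 0.0;
        double qx = px, qy = py, qz = pz;
        for (;;) {
          double s = -std::log(unif_rand()) / mumax * 10.0;
          trav += s;
          if (trav >= s_face) break;
          qx = px + trav * dx; qy = py + trav * dy; qz = pz + trav * dz;
          if (qx < blo[0] || qx > bhi[0] || qy < blo[1] || qy > bhi[1] ||
              qz < blo[2] || qz > bhi[2]) {
            if (!std::isfinite(s_face)) { trav = R_PosInf; break; }
            continue;  // may re-enter or reach the face; keep flying
          }
          double mu = dens_at(med, qx, qy, qz) * murho_tot(med, E);
          if (unif_rand() < mu / mumax) { s_int = trav; break; }
        }
        if (!std::isfinite(s_face) && !std::isfinite(s_int)) break;
      } else if (!std::isfinite(s_face)) {
        break;  // vacuum, moving away from the detector
      }
      if (s_int < s_face) {
        // real interaction
        if (mode == 1) break;  // primaries only
        px += s_int * dx; py += s_int * dy; pz += s_int * dz;
        if (unif_rand() >= murho_comp(med, E) / murho_tot(med, E))
          break;  // photoelectric absorption
        double c = kn_sample_cost(E);
        E = compton_eprime(E, c);
        rotate_dir(dx, dy, dz, c);
        if (++order > order_cap || E < ecut) break;
        continue;
      }
      // photon reaches the collimator face
      px += s_face * dx; py += s_face * dy; pz += s_face * dz;
      if (mode == 2 && order == 0) break;
      double xt, ya, dpt;
      world_to_view(f, px, py, pz, xt, ya, dpt);
      double u = xt, v = ya;
      if (u < crystal_ulo || u > crystal_uhi || v < crystal_vlo ||
          v > crystal_vhi)
        break;
      double Fx, ex, Fy, ey;
      if (!axis_zone_at(zx, u, Fx, ex) || !axis_zone_at(zy, v, Fy, ey))
        break;
      double sx = (u - ex) / Fx, sy = (v - ey) / Fy;
      double sec = std::sqrt(1 + sx * sx + sy * sy);
      double ax = (sx / sec) * f.ux + (1 / sec) * f.nx;
      double ay = (sx / sec) * f.uy + (1 / sec) * f.ny;
      double az = sy / sec;
      double cosd = dx * ax + dy * ay + dz * az;
      if (cosd <= 0) break;
      double tand = std::sqrt(std::max(0.0, 1 - cosd * cosd)) / cosd;
      double sshift = L_eff * tand;
      if (sshift < hole_d) {
        double J = sec * sec;  // spherical-capture Jacobian, shared law
        double p_acc = f_open * circle_overlap(sshift / hole_d) * J;
        double dirn2 = dx * f.nx + dy * f.ny;
        double tcr_cm = 0.1 * t_crystal / std::max(dirn2, 0.05);
        double mt = mu_crystal * tcr_cm;
        double p_det = 1.0 - std::exp(-mt);
        // mean interaction depth along the crystal path -> lateral shift
        double lbar_cm = (1.0 - (1.0 + mt) * std::exp(-mt)) /
                         (mu_crystal * p_det);
        double lbar = 10.0 * lbar_cm;
        double du = lbar * (dx * f.ux + dy * f.uy);
        double dv = lbar * dz;
        double pu = (u + du) / pitch + u_half;
        double pv = (v + dv) / pitch + v_half;
        bool any = false;
        for (int wi = 0; wi < nwin; ++wi) {
          double pw =
              window_prob(E, windows(wi, 0), windows(wi, 1), eres140);
          double val = w * p_acc * p_det * pw;
          if (val < 1e-15) continue;
          deposit2d(pi_[wi], nu, nv, pu, pv, val);
          deposit2d(pi2_[wi], nu, nv, pu, pv, val * val);
          any = true;
        }
        if (any) ++n_acc;
      }
      break;  // photon absorbed in collimator/crystal or lost
    }
  }
  return List::create(_["images"] = imgs, _["sq"] = imgs2,
                      _["n_accepted"] = (double)n_acc,
                      _["n_histories"] = (double)n_hist);
}
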