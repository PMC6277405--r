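#pragma once
#include <Rcpp.h>
#include <cmath>

// Compton kinematics and Klein-Nishina sampling.  Energies in keV.
const double MEC2 = 510.998950;  // electron rest energy, keV

inline double compton_eprime(double E, double cost) {
  return E / (1.0 + (E / MEC2) * (1.0 - cost));
}

// Unnormalized KN angular factor f(c) = (E'/E)^2 (E/E' + E'/E - sin^2),
// so that dSigma/dOmega = (re^2/2) f(c).  f <= 2 on [-1, 1].
inline double kn_f(double E, double cost) {
  double r = 1.0 / (1.0 + (E / MEC2) * (1.0 - cost));
  return r * r * (1.0 / r + r - (1.0 - cost * cost));
}

// Total KN cross-section in units of (pi re^2); absolute scale cancels in
// all pdf ratios used here.
inline double kn_total(double E) {
  double a = E / MEC2;
  double t1 = (1.0 + a) / (a * a) *
              (2.0 * (1.0 + a) / (1.0 + 2.0 * a) - std::log(1.0 + 2.0 * a) / a);
  double t2 = std::log(1.0 + 2.0 * a) / (2.0 * a);
  double t3 = (1.0 + 3.0 * a) / ((1.0 + 2.0 * a) * (1.0 + 2.0 * a));
  return 2.0 * (t1 + t2 - t3);  // sigma / (pi re^2)
}

// Probability density (per steradian) of scattering by angle with cosine c,
// times 4*pi: the anisotropy weight relative to an isotropic emitter.
inline double kn_w4pi(double E, double cost) {
  // dSigma/dOmega / Sigma * 4pi = (f/2) / (sigma/(pi re^2)) * 4  ... :
  // dS/dO = (re^2/2) f ; Sigma = pi re^2 * kn_total ; ratio*4pi = 2 f / kn_total
  return 2.0 * kn_f(E, cost) / kn_total(E);
}

// Rejection sampling of the scattering cosine from KN at energy E, using
// R's RNG (caller must hold an RNGScope).
inline double kn_sample_cost(double E) {
  for (;;) {
    double c = 2.0 * unif_rand() - 1.0;
    if (unif_rand() * 2.0 <= kn_f(E, c)) return c;
  }
}

// Rotate direction (dx,dy,dz) by polar angle with cosine `cost` and uniform
// azimuth; standard scatter-frame rotation.
inline void rotate_dir(double& dx, double& dy, double& dz, double cost) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double phi = 2.0 * M_PI * unif_rand();
  double sp = std::sin(phi), cp = std::cos(phi);
  double ux, uy, uz, vx, vy, vz;
  // build orthonormal frame around (dx,dy,dz)
  if (std::fabs(dz) < 0.99) {
    double nrm = std::sqrt(dx * dx + dy * dy);
    ux = -dy / nrm; uy = dx / nrm; uz = 0.0;
  } else {
    double nrm = std::sqrt(dy * dy + dz * dz);
    ux = 0.0; uy = -dz / nrm; uz = dy / nrm;
  }
  vx = dy * uz - dz * uy;
  vy = dz * ux - dx * uz;
  vz = dx * uy - dy * ux;
  double nx = sint * (cp * ux + sp * vx) + cost * dx;
  double ny = sint * (cp * uy + sp * vy) + cost * dy;
  double nz = sint * (cp * uz + sp * vz) + cost * dz;
  double nrm = std::sqrt(nx * nx + ny * ny + nz * nz);
  dx = nx / nrm; dy = ny / nrm; dz = nz / nrm;
}

// Gaussian energy-window detection probability: FWHM(E) scales as sqrt(E),
// anchored by the fractional FWHM at 140 keV.
inline double window_prob(double E, double lo, double hi, double eres140) {
  if (eres140 <= 0) return (E >= lo && E <= hi) ? 1.0 : 0.0;
  double fwhm = eres140 * 140.0 * std::sqrt(E / 140.0);
  double s = fwhm / 2.3548200450309493;
  double a = 0.5 * (1.0 + std::erf((hi - E) / (s * M_SQRT2)));
  double b = 0.5 * (1.0 + std::erf((lo - E) / (s * M_SQRT2)));
  return a - b;
}
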