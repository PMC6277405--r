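---
title: "Fast quantitative SPECT simulation and reconstruction for focusing collimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fast quantitative SPECT simulation and reconstruction for focusing collimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Liver radioembolization is guided by a Tc-99m MAA scout SPECT.  Making
that scan fast enough for use *during* the intervention requires more
sensitive collimation (focusing collimators) together with a forward
projector fast enough for Monte Carlo-based iterative reconstruction.
`spectsim` implements both sides of that problem: a convolution-based
forced-detection (CFD) projector with region-wise point-spread-function
(PSF) acceleration for parallel-hole, cone-beam and multifocal
collimators, OSEM reconstruction with three scatter-correction modes, a
brute-force analog Monte Carlo oracle for validation, and a digital
phantom evaluation suite (activity recovery, truncation, noise and
scan-time analysis).

## Collimator model

All collimators share LEHR hole parameters (hole length 24.05 mm,
diameter 1.11 mm, septal thickness 0.16 mm) on a 53.3 x 38.7 cm crystal,
with 3.8 mm FWHM intrinsic camera resolution.  Geometry is encoded as
per-axis affine zone maps between object transverse coordinates at depth
$z$ and detector coordinates,

$$ u = e + (x - e)\, \frac{F}{F - z}, $$

with $F$ the (signed) focal length and $e$ the expansion centre.  The
parallel collimator is the $F \to \infty$ limit; cone-beam collimators
converge both axes to a focal point at $F$ = 50 or 100 cm; the
multifocal collimator converges with $F$ = 50 cm over a centred
26.7 x 19.4 cm zone and diverges outside it.

**Derived diverging focal length.**  The diverging focal distance of the
multifocal collimator is not tabulated anywhere; we derive it by
requiring (i) hole-direction continuity at the focus/diverge boundary
and (ii) a parallel outermost hole.  Per axis this gives
$F_d = F\,(W/2 - u_1)/u_1$ behind the detector ($W$ crystal width, $u_1$
half-width of the focusing zone), about 49.8 cm.  A convenient
consequence is that the multifocal field of view then equals the
parallel-hole field of view at *every* distance, not just at one
calibration radius.

**Sensitivity and resolution.**  The parallel-hole geometric sensitivity
is derived for circular bores in hexagonal packing,
$g = \frac{\pi}{2\sqrt 3}\left(\frac{d}{d+t}\right)^2
\frac{d^2}{16\,L_e^2}$, with the septal-penetration-corrected length
$L_e = L - 2/\mu_{\mathrm{Pb}}$.  The geometric resolution is
$\mathrm{FWHM}_{geo}(z) = d\,(L_e + z)/L_e$ in the object plane.  Mapping
the collimator's spherical acceptance onto the flat detector introduces
the Jacobian $1/\cos^2\theta$ of the local hole inclination; focusing
regions additionally gain the magnification area factor $|M_x M_y|$.
Both projectors (fast and oracle) share these laws as input physics; the
oracle's independence lies in *how* detection is computed (per-photon
hole transport vs deterministic convolution), not in a different
collimator law.

## The fast projector (CFD with region-wise PSF)

For each view the activity and attenuation volumes are rotated and
warped into a detector-aligned frame in a **single trilinear
interpolation pass**: plane $z$ is scaled by the region magnification so
each constant-depth plane aligns with its detector projection.
Attenuation is accumulated along the warped fan paths (a cumulative sum
per detector column times the secant of the hole inclination), each
depth plane is convolved with one Gaussian kernel per region --- the
single-convolution-per-region acceleration; intra-region shift variance
of the PSF is deliberately ignored, as the point-source study shows it
is sub-pixel --- and the result is weighted by sensitivity, Jacobian,
crystal stopping power and dwell time.  The multifocal detector is
partitioned into nine rectangular zones (the cross product of three
zones per axis, realising the four region types); region projections are
cross-faded linearly over a two-pixel border.

The kernel combines, in quadrature, the geometric response magnified to
the detector with the intrinsic resolution:
$\sigma_{det}(z) = \sqrt{(M \cdot \mathrm{FWHM}_{geo}(z))^2 + 3.8^2}/2.355$.
Converging regions stop resolving within 5% of the focal plane
(trans-focal inverted imaging is not modeled); in practice almost no
tissue lies that deep.

Scatter is estimated by forced detection: emission sites are sampled
proportional to activity, photons undergo Woodcock tracking through the
density map with Klein-Nishina Compton sampling (photoelectric
absorption by survival weighting, scatter orders capped at 3 by
default), and at every interaction a deterministic weight

$$ w \cdot 4\pi\, p_{KN}(\theta_s) \cdot g\, J\, |M_x M_y| \cdot
   e^{-\int \mu(E')\,dl} \cdot P_{win}(E') \cdot p_{crystal} $$

is deposited at the projected detector position of the site, binned by
depth and blurred with the depth-matched PSF.  Energy windows default to
the 15% photopeak window at 140 keV ([129.5, 150.5] keV) and the 20%
scatter window at 110 keV ([99, 121] keV); the detector energy
resolution (9.9% FWHM at 140 keV, scaling as $\sqrt E$) converts true
energies into window probabilities.  The resolution value is a typical
NaI figure, configurable, and matters: it sets the photopeak scatter
fraction and hence the optimal dual-window weight.

## The Monte Carlo oracle

The oracle tracks photons analogically: isotropic emission, Woodcock
transport, Klein-Nishina scattering, then an explicit statistical
collimator-hole acceptance at the face --- the circular-bore overlap
transmission at the photon's angular deviation from the local hole axis,
the open-area fraction, the spherical-capture Jacobian, and
incidence-angle-dependent crystal stopping with the mean interaction
depth shifting (and skewing) the detected position.  Intrinsic blur is
applied afterwards.  The acceptance model integrates analytically to
exactly the fast projector's sensitivity law, which makes
fast-versus-oracle comparisons a genuine dual-route check of geometry,
broadening, warping, attenuation and scatter.

Because isotropic emission toward a ~1e-4 acceptance is hopeless at desk
scale, extended-source runs use two passes: a cone importance-sampled
primary-only pass (exact solid-angle weights; transport stays analog)
and an isotropic scatter-only pass with a history multiplier.

## Phantoms

*NEMA IEC image-quality phantom*: six spheres (10-37 mm) on a 57.2 mm
ring at a configurable uptake ratio (default 10:1) in a water-filled
elliptical shell; used for projector validation.  The lung insert of the
physical phantom is omitted (it plays no role in the profile
comparison).

*Liver/tumor/lung phantom*: a parametric anthropomorphic stand-in.  A
35 x 23 cm elliptical torso holds a ~2.1 L two-lobe liver (bulky right
lobe, thin left lobe crossing the midline, inferior caudal extension),
two ~1.6 L lungs at 0.26 g/cm3, and a 20 mm radius spherical tumor in
the anterior right lobe at a 5:1 concentration over parenchyma.  Total
activity defaults to 100 MBq with a 5% lung shunt fraction.  The
detector orbit follows the convex body outline at 1 cm clearance,
rotating about the liver centroid.

The anatomy was chosen so the study's *relative* collimator behaviour is
realistic: projection counts rank cone-beam 50 > multifocal > cone-beam
100 > parallel at ratios close to 2.1 : 1.6 : 1.4 : 1, and the cone-beam
collimators see substantially less of the lung than the parallel one.
Two caveats are inherent to a parametric stand-in and documented rather
than hidden: (i) a compact ellipsoid-union liver cannot simultaneously
reproduce a high liver truncation fraction *and* realistic sensitivity
ratios --- truncation requires large orbit radii, the sensitivity ratios
small ones; a real segmented liver reconciles them with a much larger
bounding box at equal volume.  This package's liver is fully inside the
>50%-of-views field of view of the cone-beam 50 collimator (its raw
per-view visibility still drops to ~0.6 at the caudal tip), so truncation
statements are made as liver-versus-lung inequalities.  (ii) the liver
volume (~2.1 L) exceeds a textbook 1.6 L; the extra volume buys the
bottom-heavy axial profile that produces partial coverage at all.

## Reconstruction

OSEM with the CFD system model in both forward and backward projections.
The backprojector is the *exact* adjoint of the forward operator (same
warp weights transposed, same symmetric kernels, same attenuation and
Jacobian maps); the adjointness identity
$\langle Ax, y\rangle = \langle x, A^{\!\top} y\rangle$ holds to ~1e-7
relative and is tested for all four collimators.  Defaults are 8 subsets
(angle-interleaved, view $i$ -> subset $i \bmod 8$) and 10 iterations;
initialization is uniform inside the body mask; voxels with zero
sensitivity (outside the union field of view) are frozen.

Scatter correction modes:

* `mc`: forced-detection scatter of the *current estimate* through the
  known density map, recomputed every iteration (configurable), smoothed
  with the same 2-pixel kernel used for the dual-window estimate to
  suppress Monte Carlo noise.
* `dew`: $k$ times the Gaussian-smoothed (FWHM 2 pixels; the
  sigma-vs-FWHM reading of "a Gaussian filter of two pixels" is a
  recorded interpretation) scatter-window data, constant across
  iterations.  The 15%-vs-20% window width scaling is folded into $k$.
* `none`.

`optimal_k_search()` reconstructs over a $k$ grid centred on the true
photopeak-scatter to scatter-window count ratio (available from the
simulation components) and minimizes the mean squared error against the
phantom over the liver, with one refinement pass.  With this package's
energy resolution and scatter-order defaults the optimum lands near
0.5-0.6 while the first-estimate ratio is ~0.6; reference studies report
~0.72 --- the value is sensitive to the energy-resolution model and
anatomy, which is why only the MSE ordering (optimal beats clinical) and
convexity are asserted strictly.

## Evaluation

Activity recovery is the VOI activity ratio in percent; the tumor VOI is
the label eroded by one pixel (6-connected, one pass); the background
liver VOI is the liver inside the cone-beam-50 high-sensitivity region
(geometric sensitivity above its in-liver median) and its >50% field of
view, minus the tumor; the lung VOI likewise.

Noise offers two definitions.  The default, across-realization per-voxel
SD averaged over the VOI and normalized to the VOI mean, is pure
ensemble noise and scales almost exactly as $1/\sqrt{\mathrm{counts}}$
--- which makes the equal-noise scan time the inverse count ratio.  The
scan-time analysis instead uses the in-VOI *spatial* SD: it carries a
resolution-texture floor that compresses the collimator advantage, and
it is the definition under which the package reproduces the reference
behaviour (cone-beam 50 reaching parallel-hole quality in ~70% of the
time, multifocal ~81%, cone-beam 100 ~91% at the reduced study scale).
This is a deliberate deviation from the initially planned ensemble
definition, made because the ensemble metric provably cannot show a
compressed advantage.

`equal_noise_time()` interpolates noise-versus-time curves with a
monotone piecewise-cubic (Hyman-filtered) spline and reports the time at
which each focusing collimator reaches the parallel-hole noise at
20 s/view.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the study at reduced
sizes chosen as a deliberate design point: phantoms on 64 x 64 x 46
(9.4 mm) or 48 x 48 x 34 (12.5 mm) grids instead of 128 x 128 x 90
(4.7 mm), 16-48 views instead of 120, three noise realizations instead
of ten for the scan-time curves, and 2e5-scale scatter histories.  The
projector comparison uses 2e6 cone-sampled primary histories plus an
8-fold scatter pass per collimator; the PSF study uses 1e7 histories per
point source.  All random draws go through R's RNG, so every figure is
bit-reproducible from its seed.

Other numerical choices: trilinear interpolation with zero padding for
the single warp pass; Gaussian kernels truncated at 3.5 sigma and
normalized to unit sum (making the convolution exactly self-adjoint);
midpoint cumulative attenuation; Woodcock tracking with the global
density maximum; Compton sampling by rejection against the bound
$f(c) \le 2$; scatter histories terminated below 55 keV (below both
windows) or after 3 orders (7 in the oracle); ratios in the EM update
guarded at 1e-12.

## Limitations

Septal penetration imaging, high-energy isotopes (Y-90, Ho-166
bremsstrahlung), detector dead time, respiratory motion and half-cone
collimators are out of scope.  The phantom is a parametric stand-in:
absolute truncation fractions and the exact optimal $k$ differ from
segmented-anatomy studies (see the caveats above), while orderings,
convergence behaviour, projector fidelity and the recovery ladder are
reproduced.  Scatter in the fast path shares the PSF of the central
region across regions (scatter is smooth, and the approximation is
absorbed into the oracle comparison bands).
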