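# spectsim

Simulation and quantitative reconstruction of Tc-99m liver SPECT with
focusing collimators, in R.

Interventional liver radioembolization would benefit from a SPECT scan
acquired and reconstructed *during* the procedure.  Two ingredients make
that plausible: focusing collimators (cone-beam, multifocal), which trade
field of view for sensitivity, and a forward projector fast enough to sit
inside Monte Carlo-based iterative reconstruction.  `spectsim` implements
and evaluates both:

* **Fast projector** — convolution-based forced detection (CFD): the
  object is rotated *and* warped into a detector-aligned frame in one
  trilinear pass, attenuated along the focusing-hole fan paths, and each
  depth plane is convolved with a single distance-dependent Gaussian PSF
  per collimator region, weighted by the `1/cos²θ` Jacobian and the
  region magnification.  Scatter comes from a forced-detection
  Klein–Nishina transport through the density map.
* **Monte Carlo oracle** — a brute-force analog projector with an
  explicit statistical collimator-hole transport, used to validate the
  fast path (PSF shape and position, sensitivity, full-image agreement).
* **Reconstruction** — OSEM (8 subsets × 10 iterations by default) with
  resolution recovery in forward *and* backward projections (the
  backprojector is the exact adjoint), attenuation correction, and
  scatter correction that is Monte Carlo-based (`mc`), dual-energy-window
  (`dew`, photopeak 15% @ 140 keV, scatter window 20% @ 110 keV,
  2-pixel smoothing, weight `k`), or absent.
* **Phantoms & evaluation** — NEMA IEC sphere phantom, a synthetic
  liver/tumor/lung phantom (100 MBq, 20 mm tumor at 5:1 uptake, 5% lung
  shunt), body-contour orbits, activity recovery, recovery profiles,
  field-of-view/truncation maps, noise levels and equal-noise scan-time
  analysis.

Everything is driven by R functions; a thin command line
(`inst/cli/spectsim.R`) wraps the `phantom` → `simulate` → `reconstruct`
→ `evaluate` pipeline, and `vignettes/spectsim-methods.Rmd` documents the
model, assumptions and numerical choices.

## Worked example

```r
library(spectsim)

ph    <- make_liver_phantom(grid = c(64, 64, 46), voxel_mm = 9.4)
spec  <- make_collimator("conebeam", 50)      # F = 50 cm, LEHR holes
orbit <- plan_orbit(ph, spec, n_views = 32, time_per_view = 20)

ps  <- project(ph, spec, orbit, n_scatter_histories = 2e5, seed = 5)
cnt <- add_poisson(ps, seed = 42)
cnt
#> <projection_set> counts, 57 x 41 pixels x 32 views, windows: photopeak, scatter
#>   total photopeak counts: 2.776e+06

rec <- osem(cnt, spec, orbit, ph$density,
            recon_settings(scatter_mode = "mc", mc_histories = 3e4,
                           seed = 9))
voi <- make_vois(ph, orbit)$tumor
activity_recovery(rec, ph, voi)
#> [1] 108.7552
```

The projection set holds per-view mean (or Poisson count) images for the
photopeak and scatter windows, ~87 k photopeak counts per 20 s view for
this collimator, about 30% of which are scattered photons.  The OSEM
reconstruction with Monte Carlo-based scatter correction recovers ≈109%
of the true tumor activity in the one-pixel-eroded tumor VOI — slightly
above 100% because of resolution recovery overshoot at a hot sphere;
without scatter correction the same data give ≈122%, and the
dual-energy-window variants fall in between (the scatter-correction
"recovery ladder").  `optimal_k_search()` reproduces the clinical-k
versus MSE-optimal-k comparison, and `equal_noise_time()` the scan-time
reduction of the focusing collimators.

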