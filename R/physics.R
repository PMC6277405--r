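#' Material attenuation table
#'
#' Linear attenuation coefficients (total and Compton component, per cm)
#' for water, lung (0.26 g/cm3) and air, tabulated over 50-160 keV and
#' digitized from standard reference data.  All three materials follow the
#' water mass-attenuation shape scaled by density, which is accurate in
#' this Compton-dominated energy range.
#'
#' @return A data.frame with columns `energy_keV`, `material`,
#'   `density_g_cm3`, `mu_total_cm1`, `mu_compton_cm1`.
#' @export
material_table <- function() {
  if (is.null(.spectsim_env$mat)) {
    path <- system.file("extdata", "attenuation.csv", package = "spectsim")
    .spectsim_env$mat <- read.csv(path, stringsAsFactors = FALSE)
  }
  .spectsim_env$mat
}

#' Linear attenuation coefficient of a material
#' @param material `"water"`, `"lung"` or `"air"`.
#' @param energy_keV photon energy (50-160 keV), may be a vector.
#' @param component `"total"` or `"compton"`.
#' @export
mu_of <- function(material = "water", energy_keV = 140,
                  component = c("total", "compton")) {
  component <- match.arg(component)
  tab <- material_table()
  tab <- tab[tab$material == material, ]
  if (!nrow(tab)) stop("unknown material: ", material)
  col <- if (component == "total") tab$mu_total_cm1 else tab$mu_compton_cm1
  approx(tab$energy_keV, col, xout = energy_keV, rule = 2)$y
}

# dense water mass-attenuation tables for the C++ transport (mu/rho, cm^2/g)
murho_tables <- function() {
  if (is.null(.spectsim_env$murho)) {
    E <- seq(50, 160, by = 1)
    .spectsim_env$murho <- list(
      E = E,
      tot = mu_of("water", E, "total"),
      comp = mu_of("water", E, "compton"))
  }
  .spectsim_env$murho
}

#' Energy window
#'
#' @param center_keV window centre.
#' @param relative_width full fractional width; bounds are
#'   `center * (1 +/- width/2)`.
#' @export
energy_window <- function(center_keV, relative_width) {
  stopifnot(center_keV > 0, relative_width > 0)
  structure(list(center = center_keV, width = relative_width,
                 lo = center_keV * (1 - relative_width / 2),
                 hi = center_keV * (1 + relative_width / 2)),
            class = "energy_window")
}

#' @rdname energy_window
#' @export
photopeak_window <- function() energy_window(140, 0.15)

#' @rdname energy_window
#' @export
scatter_window <- function() energy_window(110, 0.20)

#' Compton-scattered photon energy
#'
#' `E' = E / (1 + (E/mc2) (1 - cos theta))` with `mc2 = 511` keV.
#'
#' @param energy_keV incident energy.
#' @param theta scattering angle, radians (0..pi).
#' @export
compton_scatter_energy <- function(energy_keV, theta) {
  stopifnot(all(energy_keV > 0), all(theta >= 0), all(theta <= pi + 1e-12))
  energy_keV / (1 + (energy_keV / 510.99895) * (1 - cos(theta)))
}

#' Sample Compton scattering angles from the Klein-Nishina cross-section
#'
#' Rejection sampling of the scattering cosine from the Klein-Nishina
#' differential cross-section at the given energy, using R's RNG (seed with
#' [set.seed()] for reproducibility).
#'
#' @param energy_keV incident energy.
#' @param n number of samples.
#' @return Matrix with columns `cos_theta` and `energy_keV` (scattered).
#' @export
sample_compton <- function(energy_keV, n = 1) {
  cpp_sample_compton(energy_keV, as.integer(n))
}

#' Klein-Nishina angular density
#'
#' Normalized probability density of the scattering cosine,
#' `p(cos theta)`, at the given energy (integrates to 1 over \[-1, 1\]).
#' @inheritParams sample_compton
#' @param cos_theta scattering cosine(s).
#' @export
klein_nishina_pdf <- function(energy_keV, cos_theta) {
  # dSigma/dOmega ~ f(c)/2 per (pi re^2); total = kn_total; the azimuthal
  # integral contributes 2*pi
  vapply(cos_theta, function(cc) cpp_kn_f(energy_keV, cc), 0) *
    pi / (pi * cpp_kn_total(energy_keV))
}

#' Energy-window detection probability
#'
#' Probability that a photon of true energy E is recorded inside the window
#' given Gaussian energy blur whose FWHM scales with `sqrt(E)`, anchored at
#' the fractional resolution at 140 keV.
#'
#' @param energy_keV true photon energy.
#' @param window an [energy_window()].
#' @param eres140 fractional FWHM at 140 keV (0 = perfect resolution).
#' @export
window_detection_prob <- function(energy_keV, window, eres140 = 0.099) {
  stopifnot(energy_keV > 0, eres140 >= 0)
  vapply(energy_keV, function(E)
    cpp_window_prob(E, window$lo, window$hi, eres140), 0)
}

#' Line attenuation through a voxel volume
#'
#' Transmission `exp(-integral of mu dl)` along the segment `p0 -> p1`
#' using exact Siddon-type voxel traversal.  Density volumes are converted
#' to linear attenuation with the water mass-attenuation coefficient at the
#' given energy.
#'
#' @param vol a `voxel_volume` with `density` or `mu_cm` semantics.
#' @param p0,p1 world coordinates in mm (length-3).
#' @param energy_keV photon energy for density volumes.
#' @export
line_attenuation <- function(vol, p0, p1, energy_keV = 140) {
  mu <- switch(vol$semantics,
    density = vol$data * mu_of("water", energy_keV),
    mu_cm = vol$data,
    stop("volume must have density or mu_cm semantics"))
  integral <- cpp_siddon(mu, dim(vol$data), vol$voxel_mm, vol$origin,
                         as.numeric(p0), as.numeric(p1))
  exp(-integral)
}
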