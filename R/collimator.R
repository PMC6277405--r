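#' Collimator models
#'
#' All collimators share LEHR hole parameters (24.05 mm hole length, 1.11 mm
#' hole diameter, 0.16 mm septal thickness) on a 53.3 x 38.7 cm crystal.
#' `conebeam` holes converge to a focal point at `focal_length_cm` in front
#' of the collimator; `multifocal` converges with a 50 cm focal length over
#' a centred 26.7 x 19.4 cm focusing zone (half the crystal area) and
#' diverges outside it.
#'
#' The diverging focal length of the multifocal collimator is derived, not
#' tabulated: requiring the hole direction to be continuous at the
#' focus/diverge boundary and the outermost hole to be parallel gives, per
#' axis, `Fd = F * (W/2 - u1) / u1` behind the detector (`W` crystal width,
#' `u1` half-width of the focusing zone).  With that choice the multifocal
#' field of view equals the parallel-hole field of view at every distance.
#'
#' @param kind `"parallel"`, `"conebeam"` or `"multifocal"`.
#' @param focal_length_cm focal length in cm (required for `conebeam`;
#'   default 50 for `multifocal`; ignored for `parallel`).
#' @param ... overrides for any spec field (values in mm unless noted):
#'   `hole_length_mm`, `hole_diameter_mm`, `septal_mm`, `crystal_mm`
#'   (length 2), `focus_mm` (length 2), `intrinsic_fwhm_mm`,
#'   `mu_septa_cm`, `crystal_mu_cm`, `crystal_thick_mm`, `energy_res_fwhm`
#'   (fractional FWHM at 140 keV).
#' @return A `collimator_spec`.
#' @export
make_collimator <- function(kind = c("parallel", "conebeam", "multifocal"),
                            focal_length_cm = NULL, ...) {
  kind <- match.arg(kind)
  spec <- list(
    kind = kind,
    focal_mm = Inf,
    hole_length_mm = 24.05,
    hole_diameter_mm = 1.11,
    septal_mm = 0.16,
    crystal_mm = c(533, 387),
    focus_mm = c(267, 194),
    intrinsic_fwhm_mm = 3.8,
    mu_septa_cm = 26.6,      # lead at 140 keV
    crystal_mu_cm = 2.22,    # NaI(Tl) at 140 keV
    crystal_thick_mm = 9.5,
    energy_res_fwhm = 0.099  # fractional FWHM at 140 keV
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(spec))
  if (length(bad)) stop("unknown collimator fields: ", paste(bad, collapse = ", "))
  spec <- modifyList(spec, ov)
  if (kind %in% c("conebeam", "multifocal")) {
    if (is.null(focal_length_cm)) {
      if (kind == "conebeam") stop("cone-beam collimator needs a focal length")
      focal_length_cm <- 50
    }
    if (focal_length_cm <= 0) stop("focal length must be positive")
    spec$focal_mm <- focal_length_cm * 10
  }
  with(spec, {
    if (hole_length_mm <= 0 || hole_diameter_mm <= 0 || septal_mm < 0)
      stop("invalid LEHR hole parameters")
  })
  if (kind == "multifocal") {
    if (any(spec$focus_mm >= spec$crystal_mm))
      stop("multifocal focus extent must lie strictly inside the crystal")
    u1 <- spec$focus_mm / 2
    W2 <- spec$crystal_mm / 2
    spec$diverge_focal_mm <- spec$focal_mm * (W2 - u1) / u1
  } else {
    spec$diverge_focal_mm <- c(NA_real_, NA_real_)
  }
  class(spec) <- "collimator_spec"
  spec
}

#' @export
print.collimator_spec <- function(x, ...) {
  cat(sprintf("<collimator_spec> %s", x$kind))
  if (is.finite(x$focal_mm)) cat(sprintf(", F = %.0f cm", x$focal_mm / 10))
  cat(sprintf("\n  LEHR %.2f/%.2f/%.2f mm, crystal %.1f x %.1f cm\n",
              x$hole_length_mm, x$hole_diameter_mm, x$septal_mm,
              x$crystal_mm[1] / 10, x$crystal_mm[2] / 10))
  if (x$kind == "multifocal")
    cat(sprintf("  focus zone %.1f x %.1f cm, diverge F = (%.1f, %.1f) cm behind\n",
                x$focus_mm[1] / 10, x$focus_mm[2] / 10,
                x$diverge_focal_mm[1] / 10, x$diverge_focal_mm[2] / 10))
  invisible(x)
}

PARALLEL_F <- 1e12  # encodes infinite focal length in the affine zone maps

# Zone matrix for one detector axis: columns lo, hi (detector mm), F (signed
# focal length, mm; negative = diverging), e (expansion centre, mm).
axis_zones <- function(spec, axis = 1) {
  W2 <- spec$crystal_mm[axis] / 2
  if (spec$kind == "parallel")
    return(matrix(c(-W2, W2, PARALLEL_F, 0), 1, 4,
                  dimnames = list(NULL, c("lo", "hi", "F", "e"))))
  if (spec$kind == "conebeam")
    return(matrix(c(-W2, W2, spec$focal_mm, 0), 1, 4,
                  dimnames = list(NULL, c("lo", "hi", "F", "e"))))
  u1 <- spec$focus_mm[axis] / 2
  Fd <- spec$diverge_focal_mm[axis]
  # diverging expansion centres anchor at the physical crystal edge, which
  # survives crystal enlargement via expand_crystal()
  A2 <- if (!is.null(spec$anchor_mm)) spec$anchor_mm[axis] / 2 else W2
  m <- rbind(c(-W2, -u1, -Fd, -A2),
             c(-u1,  u1, spec$focal_mm, 0),
             c( u1,  W2, -Fd,  A2))
  colnames(m) <- c("lo", "hi", "F", "e")
  m
}

#' Detector regions of a collimator
#'
#' All regions as the cross product of the per-axis zones: one region for
#' parallel and cone-beam collimators, nine rectangular zones realising
#' the four region types (focus/diverge per axis) for the multifocal
#' collimator.  Each region carries its affine axis maps (`Fx`, `ex`,
#' `Fy`, `ey`), its detector rectangle and a type label.
#'
#' @param spec a `collimator_spec`.
#' @return A list of region descriptions.
#' @export
collimator_regions <- function(spec) {
  zx <- axis_zones(spec, 1)
  zy <- axis_zones(spec, 2)
  regions <- list()
  for (i in seq_len(nrow(zx)))
    for (j in seq_len(nrow(zy))) {
      fx <- zx[i, "F"]; fy <- zy[j, "F"]
      lab <- if (spec$kind != "multifocal") "single"
        else paste0(if (fx > 0) "focus_x" else "diverge_x", "_",
                    if (fy > 0) "focus_y" else "diverge_y")
      regions[[length(regions) + 1]] <-
        list(Fx = unname(fx), ex = unname(zx[i, "e"]),
             Fy = unname(fy), ey = unname(zy[j, "e"]),
             rect = c(zx[i, "lo"], zx[i, "hi"], zy[j, "lo"], zy[j, "hi"]),
             type = lab)
    }
  regions
}

#' In-plane magnification of a collimator region
#'
#' Scale factor from object transverse coordinates at depth `z_mm` (from the
#' collimator face) to detector coordinates: `M = F/(F - z)` per axis
#' (signed F; diverging zones give `M < 1`, parallel gives 1).
#'
#' @param spec a `collimator_spec`.
#' @param region region index from [collimator_regions()] (default the
#'   central/focusing region).
#' @param z_mm depth from the collimator face, mm.
#' @return Named numeric `c(x =, y =)`.
#' @export
magnification <- function(spec, region = NULL, z_mm = 0) {
  regs <- collimator_regions(spec)
  if (is.null(region)) region <- which(vapply(regs, function(r)
    r$type %in% c("single", "focus_x_focus_y"), logical(1)))[1]
  r <- regs[[region]]
  for (F in c(r$Fx, r$Fy))
    if (F > 0 && F < PARALLEL_F && any(z_mm >= F))
      stop("z beyond the focal length of a converging region")
  c(x = unname(r$Fx / (r$Fx - z_mm)), y = unname(r$Fy / (r$Fy - z_mm)))
}

# hole-axis slopes (tan of the inclination components) at a detector point
hole_slopes <- function(spec, u_mm, v_mm) {
  zx <- axis_zones(spec, 1); zy <- axis_zones(spec, 2)
  zone_of <- function(z, u) {
    i <- which(u >= z[, "lo"] - 1e-9 & u <= z[, "hi"] + 1e-9)[1]
    if (is.na(i)) stop("detector position outside the crystal")
    unname((u - z[i, "e"]) / z[i, "F"])
  }
  c(sx = zone_of(zx, u_mm), sy = zone_of(zy, v_mm))
}

#' Jacobian sensitivity factor at a detector pixel
#'
#' The mapping of the focusing collimator's sphere of acceptance onto the
#' flat detector carries a Jacobian determinant `1/cos^2(theta)`, with
#' `theta` the inclination of the hole axis reaching the pixel.
#'
#' @param spec a `collimator_spec`.
#' @param u_mm,v_mm detector coordinates in mm (0 at the crystal centre).
#' @return The factor `1/cos^2(theta) >= 1`.
#' @export
jacobian_sensitivity <- function(spec, u_mm, v_mm = 0) {
  s <- hole_slopes(spec, u_mm, v_mm)
  1 + s[["sx"]]^2 + s[["sy"]]^2
}

#' Analytic parallel-hole geometric sensitivity
#'
#' Detected fraction of an isotropic point emission through a hexagonal
#' array of circular holes: `g = p * (d/(d+t))^2 * d^2 / (16 L_eff^2)` with
#' packing fraction `p = pi/(2 sqrt 3)` and septal-penetration-corrected
#' hole length `L_eff = L - 2/mu_septa`.
#'
#' @param spec a `collimator_spec`.
#' @export
collimator_sensitivity <- function(spec) {
  d <- spec$hole_diameter_mm
  t <- spec$septal_mm
  Leff <- effective_hole_length(spec)
  open_fraction(spec) * d^2 / (16 * Leff^2)
}

effective_hole_length <- function(spec)
  spec$hole_length_mm - 2 / spec$mu_septa_cm * 10

open_fraction <- function(spec)
  pi / (2 * sqrt(3)) *
    (spec$hole_diameter_mm / (spec$hole_diameter_mm + spec$septal_mm))^2

#' Geometric collimator resolution at depth z
#'
#' FWHM of the geometric hole response in the object plane:
#' `d * (L_eff + z) / L_eff`.
#' @param spec a `collimator_spec`.
#' @param z_mm depth from the collimator face, mm.
#' @export
geometric_fwhm <- function(spec, z_mm) {
  Leff <- effective_hole_length(spec)
  spec$hole_diameter_mm * (Leff + z_mm) / Leff
}

#' Region PSF kernel at depth z
#'
#' One Gaussian detection kernel per collimator region and depth plane (the
#' single-convolution-per-region acceleration): the object-plane FWHM
#' combines, in quadrature, the geometric collimator response with the
#' intrinsic camera resolution demagnified to the object plane.  The kernel
#' is normalized so that its sum equals the region's geometric sensitivity
#' (analytic parallel-hole sensitivity times the mean Jacobian factor of
#' the region).
#'
#' @param spec a `collimator_spec`.
#' @param region region index from [collimator_regions()].
#' @param z_mm depth from the collimator face, mm (scalar, >= 0).
#' @param pitch_mm object-plane pixel pitch, mm.
#' @return List with `kernel` (2D matrix), `sensitivity` (its sum),
#'   `fwhm_mm` (per-axis object-plane FWHM).
#' @export
psf_kernel <- function(spec, region = NULL, z_mm, pitch_mm) {
  stopifnot(z_mm >= 0, pitch_mm > 0)
  regs <- collimator_regions(spec)
  if (is.null(region)) region <- which(vapply(regs, function(r)
    r$type %in% c("single", "focus_x_focus_y"), logical(1)))[1]
  r <- regs[[region]]
  M <- abs(c(r$Fx / (r$Fx - z_mm), r$Fy / (r$Fy - z_mm)))
  fwhm <- sqrt(geometric_fwhm(spec, z_mm)^2 +
               (spec$intrinsic_fwhm_mm / M)^2)
  sig_px <- fwhm / 2.3548 / pitch_mm
  h <- pmax(1, ceiling(3.5 * sig_px))
  if (any(2 * h * pitch_mm > spec$crystal_mm))
    stop("kernel support exceeds the detector extent")
  g1 <- function(s, hh) {
    k <- exp(-0.5 * ((-hh):hh)^2 / s^2)
    k / sum(k)
  }
  ker <- outer(g1(sig_px[1], h[1]), g1(sig_px[2], h[2]))
  sens <- collimator_sensitivity(spec) * region_mean_jacobian(spec, r)
  list(kernel = ker * sens, sensitivity = sens, fwhm_mm = fwhm)
}

region_mean_jacobian <- function(spec, r) {
  us <- seq(r$rect[1], r$rect[2], length.out = 21)
  vs <- seq(r$rect[3], r$rect[4], length.out = 21)
  sx <- (us - r$ex) / r$Fx
  sy <- (vs - r$ey) / r$Fy
  mean(outer(sx^2, sy^2, function(a, b) 1 + a + b))
}

# Per-region detector weight maps with a linear cross-fade over a two-pixel
# band at every interior zone boundary (the region "averaging" border).
region_weights <- function(spec, nu, nv, pitch) {
  u <- (seq_len(nu) - (nu + 1) / 2) * pitch
  v <- (seq_len(nv) - (nv + 1) / 2) * pitch
  zx <- axis_zones(spec, 1); zy <- axis_zones(spec, 2)
  axis_w <- function(z, x) {
    n <- nrow(z)
    sapply(seq_len(n), function(i) {
      w <- rep(1, length(x))
      if (i > 1) {  # interior lower boundary
        b <- z[i, "lo"]
        w <- pmin(w, pmax(0, pmin(1, (x - (b - pitch)) / (2 * pitch))))
      } else w <- pmin(w, as.numeric(x >= z[i, "lo"] - pitch))
      if (i < n) {  # interior upper boundary
        b <- z[i, "hi"]
        w <- pmin(w, pmax(0, pmin(1, ((b + pitch) - x) / (2 * pitch))))
      } else w <- pmin(w, as.numeric(x <= z[i, "hi"] + pitch))
      w
    })
  }
  wx <- axis_w(zx, u)  # nu x nzones_x
  wy <- axis_w(zy, v)
  regs <- collimator_regions(spec)
  out <- vector("list", length(regs))
  k <- 0
  for (i in seq_len(nrow(zx)))
    for (j in seq_len(nrow(zy))) {
      k <- k + 1
      out[[k]] <- outer(wx[, i], wy[, j])
    }
  names(out) <- vapply(regs, `[[`, "", "type")
  out
}

#' Detector region map
#'
#' Assigns each detector pixel to a collimator region and flags the
#' two-pixel blending border between regions.
#'
#' @param spec a `collimator_spec`.
#' @param nu,nv detector grid size in pixels.
#' @param pitch_mm detector pixel pitch, mm.
#' @return List with `region_id` (integer matrix), `blend_mask` (logical
#'   matrix), `types` (region labels).
#' @export
region_map <- function(spec, nu, nv, pitch_mm) {
  w <- region_weights(spec, nu, nv, pitch_mm)
  arr <- simplify2array(w)               # nu x nv x nregions
  id <- apply(arr, c(1, 2), which.max)
  blend <- apply(arr, c(1, 2), function(x) any(x > 1e-9 & x < 1 - 1e-9))
  list(region_id = id, blend_mask = blend,
       types = vapply(collimator_regions(spec), `[[`, "", "type"))
}

#' Fraction-of-views visibility map
#'
#' For each voxel, the fraction of orbit views in which its projection
#' (through the region magnification) lands inside the crystal.  The
#' artifact-free field of view is conventionally `fraction > 0.5`.
#'
#' @param spec a `collimator_spec`.
#' @param orbit a `detector_orbit`.
#' @param grid a `voxel_volume` defining the grid.
#' @return A `voxel_volume` with `fraction` semantics.
#' @export
fov_fraction_map <- function(spec, orbit, grid) {
  fr <- cpp_fov_fraction(dim(grid$data), grid$voxel_mm, grid$origin,
                         orbit$center, orbit$views$angle_deg * pi / 180,
                         orbit$views$radius_mm,
                         axis_zones(spec, 1), axis_zones(spec, 2))
  voxel_volume(fr, grid$voxel_mm, grid$origin, "fraction")
}

#' Geometric sensitivity map over a volume
#'
#' View-averaged relative point-source sensitivity (Jacobian times
#' magnification area factor for the zone seeing the voxel; 0 when unseen).
#'
#' @inheritParams fov_fraction_map
#' @export
sensitivity_map <- function(spec, orbit, grid) {
  s <- cpp_sens_map(dim(grid$data), grid$voxel_mm, grid$origin,
                    orbit$center, orbit$views$angle_deg * pi / 180,
                    orbit$views$radius_mm,
                    axis_zones(spec, 1), axis_zones(spec, 2))
  voxel_volume(s, grid$voxel_mm, grid$origin, "fraction")
}
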