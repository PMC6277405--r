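# Fast CFD forward projector and the analog Monte Carlo oracle.

# Acquisition geometry: detector grid at the projection pixel pitch (equal
# to the reconstruction voxel size by default) and the number of depth
# planes needed to cover the volume from any view.
acq_geometry <- function(spec, orbit, vol, pitch = NULL) {
  if (is.null(pitch)) pitch <- vol$voxel_mm
  nu <- max(3L, as.integer(round(spec$crystal_mm[1] / pitch)))
  nv <- max(3L, as.integer(round(spec$crystal_mm[2] / pitch)))
  half_diag <- 0.5 * sqrt(sum((dim(vol$data) * vol$voxel_mm)^2))
  nd <- as.integer(ceiling((max(orbit$views$radius_mm) + half_diag) / pitch))
  list(nu = nu, nv = nv, nd = nd, pitch = pitch)
}

#' Precompute the PSF bank for an acquisition
#'
#' Per collimator region: detector-frame Gaussian sigmas per depth plane
#' (geometric response magnified to the detector, intrinsic resolution in
#' quadrature), the per-pixel Jacobian and crystal-stopping maps, and the
#' region blend weights.
#'
#' @param spec a `collimator_spec`.
#' @param orbit a `detector_orbit`.
#' @param vol a `voxel_volume` defining grid and pitch.
#' @param pitch_mm detector pixel pitch (default: the voxel size).
#' @return A `psf_bank`.
#' @export
make_psf_bank <- function(spec, orbit, vol, pitch_mm = NULL) {
  geo <- acq_geometry(spec, orbit, vol, pitch_mm)
  regs <- collimator_regions(spec)
  w <- region_weights(spec, geo$nu, geo$nv, geo$pitch)
  d <- (seq_len(geo$nd) - 0.5) * geo$pitch
  u <- (seq_len(geo$nu) - (geo$nu + 1) / 2) * geo$pitch
  v <- (seq_len(geo$nv) - (geo$nv + 1) / 2) * geo$pitch
  fwhm_geo <- geometric_fwhm(spec, d)
  per_reg <- lapply(regs, function(r) {
    Mx <- abs(r$Fx / (r$Fx - d)); My <- abs(r$Fy / (r$Fy - d))
    sigx <- sqrt((Mx * fwhm_geo)^2 + spec$intrinsic_fwhm_mm^2) / 2.3548 / geo$pitch
    sigy <- sqrt((My * fwhm_geo)^2 + spec$intrinsic_fwhm_mm^2) / 2.3548 / geo$pitch
    # cap the kernel where a converging region approaches its focal plane
    sigx[!is.finite(sigx)] <- 0; sigy[!is.finite(sigy)] <- 0
    sigx <- pmin(sigx, geo$nu / 4); sigy <- pmin(sigy, geo$nv / 4)
    sx <- (u - r$ex) / r$Fx
    sy <- (v - r$ey) / r$Fy
    J <- outer(sx^2, sy^2, function(a, b) 1 + a + b)
    sec <- sqrt(J)
    pdet <- 1 - exp(-spec$crystal_mu_cm * 0.1 * spec$crystal_thick_mm * sec)
    list(Fx = r$Fx, ex = r$ex, Fy = r$Fy, ey = r$ey, type = r$type,
         sigx = sigx, sigy = sigy, J = J, sec = sec, pdet = pdet)
  })
  structure(list(regions = per_reg, weights = w,
                 g = collimator_sensitivity(spec),
                 nu = geo$nu, nv = geo$nv, nd = geo$nd, pitch = geo$pitch,
                 spec = spec),
            class = "psf_bank")
}

#' Rotate and warp a volume into the detector-aligned frame of one view
#'
#' Single trilinear interpolation pass combining the view rotation about the
#' orbit centre with the per-plane magnification of the chosen collimator
#' region, so every constant-depth plane is aligned with its detector
#' projection.
#'
#' @param vol a `voxel_volume`.
#' @param orbit a `detector_orbit`.
#' @param view view index.
#' @param spec a `collimator_spec`.
#' @param region region index from [collimator_regions()] (default the
#'   central/focusing region).
#' @param pitch_mm detector pixel pitch (default: the voxel size).
#' @return 3D array `(nu, nv, nd)` in the warped frame.
#' @export
rotate_warp <- function(vol, orbit, view, spec, region = NULL,
                        pitch_mm = NULL) {
  geo <- acq_geometry(spec, orbit, vol, pitch_mm)
  regs <- collimator_regions(spec)
  if (is.null(region)) region <- which(vapply(regs, function(r)
    r$type %in% c("single", "focus_x_focus_y"), logical(1)))[1]
  r <- regs[[region]]
  vrow <- orbit$views[view, ]
  cpp_warp(vol$data, dim(vol$data), vol$voxel_mm, vol$origin, orbit$center,
           vrow$angle_deg * pi / 180, vrow$radius_mm,
           r$Fx, r$ex, r$Fy, r$ey, geo$nu, geo$nv, geo$nd, geo$pitch)
}

# forward projection of one view: activity (Bq/voxel) + attenuation map
# (per cm) -> mean detected counts per pixel (before window factors)
fp_view <- function(act, mu, vol_meta, orbit, view, bank) {
  if (!identical(dim(act), vol_meta$dim) || !identical(dim(mu), vol_meta$dim))
    stop("inconsistent grids: activity and density must share shape/pitch")
  vrow <- orbit$views[view, ]
  phi <- vrow$angle_deg * pi / 180
  P <- matrix(0, bank$nu, bank$nv)
  for (k in seq_along(bank$regions)) {
    r <- bank$regions[[k]]
    aw <- cpp_warp(act, vol_meta$dim, vol_meta$vox, vol_meta$origin,
                   orbit$center, phi, vrow$radius_mm, r$Fx, r$ex, r$Fy, r$ey,
                   bank$nu, bank$nv, bank$nd, bank$pitch)
    mw <- cpp_warp(mu, vol_meta$dim, vol_meta$vox, vol_meta$origin,
                   orbit$center, phi, vrow$radius_mm, r$Fx, r$ex, r$Fy, r$ey,
                   bank$nu, bank$nv, bank$nd, bank$pitch)
    Tw <- cpp_cumatt(mw, r$sec, bank$pitch)
    A <- cpp_gauss_stack(aw * Tw, r$sigx, r$sigy)
    P <- P + bank$weights[[k]] * cpp_plane_sum(A) * r$J * r$pdet
  }
  P * (bank$g * vrow$time_s)
}

# exact adjoint of fp_view
bp_view <- function(y, mu, vol_meta, orbit, view, bank) {
  vrow <- orbit$views[view, ]
  phi <- vrow$angle_deg * pi / 180
  out <- array(0, vol_meta$dim)
  y1 <- y * (bank$g * vrow$time_s)
  for (k in seq_along(bank$regions)) {
    r <- bank$regions[[k]]
    yr <- y1 * bank$weights[[k]] * r$J * r$pdet
    stack <- cpp_plane_bcast(yr, bank$nd)
    stack <- cpp_gauss_stack(stack, r$sigx, r$sigy)
    mw <- cpp_warp(mu, vol_meta$dim, vol_meta$vox, vol_meta$origin,
                   orbit$center, phi, vrow$radius_mm, r$Fx, r$ex, r$Fy, r$ey,
                   bank$nu, bank$nv, bank$nd, bank$pitch)
    Tw <- cpp_cumatt(mw, r$sec, bank$pitch)
    out <- out + cpp_warp_adjoint(stack * Tw, vol_meta$dim, vol_meta$vox,
                                  vol_meta$origin, orbit$center, phi,
                                  vrow$radius_mm, r$Fx, r$ex, r$Fy, r$ey,
                                  bank$nu, bank$nv, bank$nd, bank$pitch)
  }
  out
}

vol_meta_of <- function(vol)
  list(dim = dim(vol$data), vox = vol$voxel_mm, origin = vol$origin)

mu_volume <- function(density_vol, energy_keV = 140)
  density_vol$data * mu_of("water", energy_keV)

#' CFD primary-photon projection of one view
#'
#' Deterministic mean photopeak projection of unscattered photons: warp the
#' activity and attenuation maps, attenuate along the fan paths, convolve
#' each depth plane with the region PSF, weight by the Jacobian, crystal
#' stopping and sensitivity, and cross-fade regions over the blend border.
#'
#' @param bundle a `phantom_bundle` (or list with `activity` and `density`
#'   voxel volumes).
#' @param spec a `collimator_spec`.
#' @param orbit a `detector_orbit`.
#' @param view view index.
#' @param bank optional precomputed [make_psf_bank()] result.
#' @param window optional [energy_window()]; when given, the projection is
#'   scaled by the photopeak detection probability of 140 keV photons.
#' @return Matrix `(nu, nv)` of mean counts.
#' @export
cfd_primary <- function(bundle, spec, orbit, view, bank = NULL,
                        window = NULL) {
  if (is.null(bank)) bank <- make_psf_bank(spec, orbit, bundle$activity)
  P <- fp_view(bundle$activity$data, mu_volume(bundle$density),
               vol_meta_of(bundle$activity), orbit, view, bank)
  if (!is.null(window))
    P <- P * window_detection_prob(140, window, spec$energy_res_fwhm)
  P
}

#' Forced-detection Monte Carlo scatter projection
#'
#' Samples emission sites proportional to activity, transports photons
#' through the density map with Klein-Nishina Compton scattering (orders 1
#' to `order_cap`; photoelectric absorption by survival weighting), and at
#' every interaction deposits the deterministic forced-detection weight
#' toward each view in each energy window.  Depth-binned deposits are
#' blurred with the distance-dependent PSF of the central region.
#' Seed R's RNG for reproducibility.
#'
#' @param bundle a `phantom_bundle`.
#' @param spec a `collimator_spec`.
#' @param orbit a `detector_orbit`.
#' @param n_histories number of photon histories.
#' @param windows list of [energy_window()]s.
#' @param activity optional `voxel_volume` overriding `bundle$activity`
#'   (used by the reconstruction-side scatter estimate).
#' @param bank optional precomputed PSF bank.
#' @param order_cap maximum scatter order (default 3).
#' @param ndbins number of depth bins for the PSF blur (default 6).
#' @return List of `(nu, nv, n_views)` arrays of mean counts, one per
#'   window.
#' @export
cfd_scatter <- function(bundle, spec, orbit, n_histories = 2e4,
                        windows = list(photopeak = photopeak_window(),
                                       scatter = scatter_window()),
                        activity = NULL, bank = NULL, order_cap = 3,
                        ndbins = 6) {
  stopifnot(n_histories > 0)
  act <- if (is.null(activity)) bundle$activity else activity
  if (is.null(bank)) bank <- make_psf_bank(spec, orbit, act)
  tab <- murho_tables()
  cum <- cumsum(as.numeric(act$data))
  atot <- cum[length(cum)]
  winm <- do.call(rbind, lapply(windows, function(w) c(w$lo, w$hi)))
  dmax <- bank$nd * bank$pitch
  if (atot <= 0) {
    z <- array(0, c(bank$nu, bank$nv, orbit$n_views))
    return(stats::setNames(rep(list(z), length(windows)), names(windows)))
  }
  raw <- cpp_mc_scatter(cum, dim(act$data), act$voxel_mm, act$origin,
                        bundle$density$data, orbit$center,
                        orbit$views$angle_deg * pi / 180,
                        orbit$views$radius_mm,
                        axis_zones(spec, 1), axis_zones(spec, 2),
                        collimator_sensitivity(spec), winm,
                        spec$energy_res_fwhm, tab$E, tab$tot, tab$comp,
                        140, 55, as.integer(order_cap),
                        as.integer(n_histories), bank$nu, bank$nv,
                        bank$pitch, as.integer(ndbins), dmax,
                        spec$crystal_mu_cm, spec$crystal_thick_mm)
  # blur depth bins with the central-region PSF and collapse
  regs <- bank$regions
  cidx <- which(vapply(regs, function(r)
    r$type %in% c("single", "focus_x_focus_y"), logical(1)))[1]
  r <- regs[[cidx]]
  dbin <- (seq_len(ndbins) - 0.5) * dmax / ndbins
  plane_idx <- pmin(bank$nd, pmax(1, round(dbin / bank$pitch + 0.5)))
  out <- lapply(seq_along(windows), function(wi) {
    a <- raw[[wi]]
    res <- array(0, c(bank$nu, bank$nv, orbit$n_views))
    for (v in seq_len(orbit$n_views)) {
      acc <- matrix(0, bank$nu, bank$nv)
      for (b in seq_len(ndbins)) {
        pl <- a[, , b, v]
        if (!any(pl != 0)) next
        pi_ <- plane_idx[b]
        acc <- acc + cpp_gauss2d(pl, r$sigx[pi_], r$sigy[pi_])
      }
      res[, , v] <- acc * (atot * orbit$views$time_s[v])
    }
    res
  })
  names(out) <- names(windows)
  out
}

#' Simulate a full mean projection set
#'
#' Photopeak mean = CFD primaries (times the photopeak detection
#' probability) plus forced-detection scatter; scatter-window mean =
#' scatter plus the energy-blur tail of the primaries.
#'
#' @param bundle a `phantom_bundle`.
#' @param spec a `collimator_spec`.
#' @param orbit a `detector_orbit`.
#' @param n_scatter_histories Monte Carlo budget for the scatter component
#'   (0 disables scatter).
#' @param seed optional RNG seed for the scatter transport.
#' @param order_cap maximum scatter order.
#' @return A `projection_set` of kind `"mean"`, with the true primary and
#'   scatter components retained in `$components`.
#' @export
project <- function(bundle, spec, orbit, n_scatter_histories = 2e4,
                    seed = NULL, order_cap = 3) {
  bank <- make_psf_bank(spec, orbit, bundle$activity)
  pp <- photopeak_window()
  sw <- scatter_window()
  f_pp <- window_detection_prob(140, pp, spec$energy_res_fwhm)
  f_sw <- window_detection_prob(140, sw, spec$energy_res_fwhm)
  mu <- mu_volume(bundle$density)
  meta <- vol_meta_of(bundle$activity)
  nviews <- orbit$n_views
  prim <- array(0, c(bank$nu, bank$nv, nviews))
  for (v in seq_len(nviews))
    prim[, , v] <- fp_view(bundle$activity$data, mu, meta, orbit, v, bank)
  if (n_scatter_histories > 0) {
    if (!is.null(seed)) set.seed(seed)
    sc <- cfd_scatter(bundle, spec, orbit, n_scatter_histories,
                      windows = list(photopeak = pp, scatter = sw),
                      bank = bank, order_cap = order_cap)
  } else {
    z <- array(0, dim(prim))
    sc <- list(photopeak = z, scatter = z)
  }
  structure(list(
    windows = list(photopeak = prim * f_pp + sc$photopeak,
                   scatter = prim * f_sw + sc$scatter),
    kind = "mean", orbit = orbit, spec = spec, pitch = bank$pitch,
    components = list(primary_pp = prim * f_pp, scatter_pp = sc$photopeak,
                      primary_sw = prim * f_sw, scatter_sw = sc$scatter),
    meta = list(seed = seed, n_scatter_histories = n_scatter_histories)),
    class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$windows[[1]])
  cat(sprintf("<projection_set> %s, %d x %d pixels x %d views, windows: %s\n",
              x$kind, d[1], d[2], d[3],
              paste(names(x$windows), collapse = ", ")))
  cat(sprintf("  total photopeak counts: %.4g\n", sum(x$windows$photopeak)))
  invisible(x)
}

#' Draw Poisson noise on a mean projection set
#'
#' @param ps a `projection_set` of kind `"mean"`.
#' @param seed RNG seed (recorded in the result).
#' @return A `projection_set` of kind `"counts"`.
#' @export
add_poisson <- function(ps, seed = 1) {
  stopifnot(inherits(ps, "projection_set"), ps$kind == "mean")
  if (any(vapply(ps$windows, function(w) any(w < 0), logical(1))))
    stop("negative means")
  set.seed(seed)
  out <- ps
  out$windows <- lapply(ps$windows, function(w) {
    cnt <- array(rpois(length(w), w), dim(w))
    storage.mode(cnt) <- "double"
    cnt
  })
  out$kind <- "counts"
  out$meta$poisson_seed <- seed
  out
}

#' Brute-force Monte Carlo oracle projection of one view
#'
#' Analog photon tracking with an explicit statistical collimator-hole
#' transport; used as the validation oracle for the fast projector.  For
#' extended sources with a medium two passes are run: a cone
#' importance-sampled primary pass and an isotropic scatter pass (exact
#' emission weights, analog transport).
#'
#' @param x a `phantom_bundle`, or a length-3 numeric world position (mm)
#'   for a point source (then `vacuum = TRUE` drops the medium).
#' @param spec a `collimator_spec`.
#' @param orbit a `detector_orbit`.
#' @param view view index.
#' @param n_photons histories per pass.
#' @param activity_bq,time_s scaling to mean counts (defaults: the bundle's
#'   total activity and the view dwell time; 1 for point sources).
#' @param include_scatter run the scatter pass (ignored in vacuum).
#' @param scatter_mult history multiplier for the isotropic scatter pass
#'   (its acceptance probability is far below the cone-sampled primary
#'   pass).
#' @param intrinsic_blur apply the intrinsic camera resolution.
#' @param vacuum drop the medium (point sources in air).
#' @param pitch_mm detector pixel pitch.
#' @return List with per-window mean-count images (`photopeak`,
#'   `scatter`), standard-error image `se_photopeak`, and acceptance
#'   bookkeeping.
#' @export
mc_oracle_project <- function(x, spec, orbit, view = 1, n_photons = 1e6,
                              activity_bq = NULL, time_s = NULL,
                              include_scatter = TRUE, intrinsic_blur = TRUE,
                              vacuum = FALSE, pitch_mm = NULL,
                              scatter_mult = 8) {
  stopifnot(n_photons > 0)
  point_mode <- is.numeric(x) && length(x) == 3
  tab <- murho_tables()
  vol <- if (point_mode) NULL else x$activity
  if (is.null(pitch_mm))
    pitch_mm <- if (point_mode) 4.7 else vol$voxel_mm
  nu <- max(3L, as.integer(round(spec$crystal_mm[1] / pitch_mm)))
  nv <- max(3L, as.integer(round(spec$crystal_mm[2] / pitch_mm)))
  vrow <- orbit$views[view, ]
  phi <- vrow$angle_deg * pi / 180
  if (is.null(time_s)) time_s <- if (point_mode) 1 else vrow$time_s
  if (is.null(activity_bq))
    activity_bq <- if (point_mode) 1 else sum(vol$data)
  winm <- rbind(c(photopeak_window()$lo, photopeak_window()$hi),
                c(scatter_window()$lo, scatter_window()$hi))
  zx <- axis_zones(spec, 1); zy <- axis_zones(spec, 2)
  if (point_mode) {
    src <- as.numeric(x)
    cum <- numeric(0)
    dm <- c(2L, 2L, 2L); vox <- 1; org <- c(0, 0, 0)
    dens <- if (vacuum) numeric(0) else stop("point sources need vacuum=TRUE")
  } else {
    src <- numeric(0)
    cum <- cumsum(as.numeric(vol$data))
    dm <- dim(vol$data); vox <- vol$voxel_mm; org <- vol$origin
    dens <- if (vacuum) numeric(0) else as.numeric(x$density$data)
  }
  run <- function(mode, n) {
    cpp_mc_oracle(src, cum, dm, vox, org, dens, orbit$center, phi,
                  vrow$radius_mm, zx, zy,
                  spec$hole_diameter_mm, effective_hole_length(spec),
                  open_fraction(spec), spec$crystal_mu_cm,
                  spec$crystal_thick_mm, winm, spec$energy_res_fwhm,
                  tab$E, tab$tot, tab$comp, 140, 55, 7L,
                  as.integer(mode), as.integer(n), nu, nv, pitch_mm)
  }
  has_medium <- length(dens) > 0
  r1 <- run(1, n_photons)  # primaries, cone-sampled
  scale1 <- activity_bq * time_s / r1$n_histories
  img <- lapply(r1$images, function(m) m * scale1)
  sq <- lapply(r1$sq, function(m) m * scale1^2)
  n_acc <- r1$n_accepted
  if (has_medium && include_scatter) {
    # the isotropic scatter pass has a tiny acceptance probability; give it
    # more histories so its per-pixel granularity matches the primary pass
    r2 <- run(2, n_photons * scatter_mult)
    scale2 <- activity_bq * time_s / r2$n_histories
    img <- Map(function(a, b) a + b * scale2, img, r2$images)
    sq <- Map(function(a, b) a + b * scale2^2, sq, r2$sq)
    n_acc <- n_acc + r2$n_accepted
  }
  if (intrinsic_blur) {
    s <- spec$intrinsic_fwhm_mm / 2.3548 / pitch_mm
    img <- lapply(img, cpp_gauss2d, sigx = s, sigy = s)
    # blur reduces per-pixel variance; keep the unblurred sums as a
    # conservative (upper) error estimate, redistributed with the signal
    sq <- lapply(sq, cpp_gauss2d, sigx = s, sigy = s)
  }
  list(photopeak = img[[1]], scatter = img[[2]],
       se_photopeak = sqrt(pmax(sq[[1]], 0)),
       n_accepted = n_acc, nu = nu, nv = nv, pitch = pitch_mm)
}
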