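# Digital phantom generation: all evaluation inputs are produced in code.

phantom_grids <- function(grid, voxel_mm) {
  stopifnot(length(grid) == 3, all(grid >= 8), voxel_mm > 0)
  org <- -(grid - 1) / 2 * voxel_mm
  ax <- lapply(1:3, function(a) org[a] + (seq_len(grid[a]) - 1) * voxel_mm)
  list(origin = org, x = ax[[1]], y = ax[[2]], z = ax[[3]])
}

# voxel-centre membership of an ellipsoid
in_ellipsoid <- function(g, center, half) {
  arr <- array(0, c(length(g$x), length(g$y), length(g$z)))
  ex <- ((g$x - center[1]) / half[1])^2
  ey <- ((g$y - center[2]) / half[2])^2
  ez <- ((g$z - center[3]) / half[3])^2
  for (k in seq_along(g$z))
    arr[, , k] <- outer(ex, ey, `+`) + ez[k]
  arr < 1
}

in_elliptic_cylinder <- function(g, center_xy, half_xy, z_range = NULL) {
  ex <- ((g$x - center_xy[1]) / half_xy[1])^2
  ey <- ((g$y - center_xy[2]) / half_xy[2])^2
  disk <- outer(ex, ey, `+`) < 1
  arr <- array(FALSE, c(length(g$x), length(g$y), length(g$z)))
  for (k in seq_along(g$z)) {
    ok <- is.null(z_range) || (g$z[k] >= z_range[1] && g$z[k] <= z_range[2])
    if (ok) arr[, , k] <- disk
  }
  arr
}

#' NEMA IEC image-quality phantom
#'
#' Six spheres (diameters 10, 13, 17, 22, 28, 37 mm) on a 57.2 mm radius
#' ring in the axial mid-plane of a water-filled elliptical body shell
#' (half-axes 150 x 110 mm, 180 mm long), filled at
#' `sphere_to_background_ratio` times the background concentration.
#'
#' @param grid grid size, length 3 (default `c(128, 128, 90)`).
#' @param sphere_to_background_ratio sphere:background concentration ratio.
#' @param voxel_mm isotropic voxel size, mm.
#' @param total_MBq total activity in the phantom.
#' @return A `phantom_bundle`: activity, density and label `voxel_volume`s
#'   plus the body contour used for orbit planning.
#' @export
make_nema_phantom <- function(grid = c(128, 128, 90),
                              sphere_to_background_ratio = 10,
                              voxel_mm = 4.7, total_MBq = 50) {
  stopifnot(sphere_to_background_ratio > 0)
  g <- phantom_grids(grid, voxel_mm)
  shell_half <- c(150, 110)
  shell_len <- 180
  if (diff(range(g$x)) < 2 * shell_half[1] ||
      diff(range(g$y)) < 2 * shell_half[2] ||
      diff(range(g$z)) < shell_len)
    stop("grid too small to contain the NEMA body shell")
  body <- in_elliptic_cylinder(g, c(0, 0), shell_half,
                               c(-shell_len / 2, shell_len / 2))
  spheres <- array(FALSE, grid)
  diam <- c(10, 13, 17, 22, 28, 37)
  ang <- (seq_along(diam) - 1) * pi / 3
  for (i in seq_along(diam)) {
    cen <- c(57.2 * cos(ang[i]), 57.2 * sin(ang[i]), 0)
    spheres <- spheres | in_ellipsoid(g, cen, rep(diam[i] / 2, 3))
  }
  spheres <- spheres & body
  act <- array(0, grid)
  act[body] <- 1
  act[spheres] <- sphere_to_background_ratio
  act <- act * (total_MBq * 1e6 / sum(act))
  dens <- array(0.0012, grid)
  dens[body] <- 1.0
  lab <- array(0L, grid)
  lab[body] <- 1L
  lab[spheres] <- 2L
  new_phantom_bundle(act, dens, lab, voxel_mm, g$origin,
                     sphere_diam_mm = diam,
                     rotation_center_mm = c(0, 0, 0))
}

#' Synthetic liver/tumor/lung phantom
#'
#' A parametric anthropomorphic stand-in for liver radioembolization
#' imaging: an elliptical body (half-axes 180 x 125 mm), a ~1.6 L liver
#' ellipsoid offset to the patient's right in the lower half of the grid,
#' two ~1.7 L lungs (density 0.26 g/cm3) above it, and a spherical tumor
#' inside the liver.  The lung receives `lsf` of the total activity
#' uniformly; the rest goes to the liver with the tumor at
#' `tumor_uptake_ratio` times the parenchymal concentration.
#'
#' @param grid grid size, length 3 (default `c(128, 128, 90)`).
#' @param voxel_mm isotropic voxel size, mm (default 4.7).
#' @param total_MBq total phantom activity (default 100).
#' @param tumor_radius_mm tumor radius (default 20).
#' @param tumor_uptake_ratio tumor:parenchyma concentration (default 5).
#' @param lsf lung shunt fraction in `[0, 1)` (default 0.05).
#' @return A `phantom_bundle`.
#' @export
make_liver_phantom <- function(grid = c(128, 128, 90), voxel_mm = 4.7,
                               total_MBq = 100, tumor_radius_mm = 20,
                               tumor_uptake_ratio = 5, lsf = 0.05) {
  stopifnot(lsf >= 0, lsf < 1, tumor_radius_mm > 0, tumor_uptake_ratio > 0)
  g <- phantom_grids(grid, voxel_mm)
  body <- in_elliptic_cylinder(g, c(0, 0), c(175, 115))
  # ~1.6 L two-lobe liver: a bulky right lobe plus a thin left lobe
  # extending across the midline (the extension is what the cone-beam
  # 50 cm field of view clips, as for a real liver)
  rlobe_c <- c(85, 10, -5); rlobe_half <- c(58, 54, 55)
  llobe_c <- c(-30, -15, -10); llobe_half <- c(85, 42, 28)
  caudal_c <- c(80, 10, -132); caudal_half <- c(58, 54, 78)
  liver <- (in_ellipsoid(g, rlobe_c, rlobe_half) |
            in_ellipsoid(g, llobe_c, llobe_half) |
            in_ellipsoid(g, caudal_c, caudal_half)) & body
  liver_c <- rlobe_c
  tumor_c <- c(95, -12, -10)  # anterior-right, inside the right lobe
  rlobe_half_chk <- rlobe_half
  tq <- sum(((tumor_c - rlobe_c) / rlobe_half_chk)^2)
  if (sqrt(tq) + tumor_radius_mm / min(rlobe_half) > 1)
    stop("tumor does not fit inside the liver")
  tumor <- in_ellipsoid(g, tumor_c, rep(tumor_radius_mm, 3)) & liver
  lungL <- in_ellipsoid(g, c(-75, 0, 100), c(55, 70, 105)) & body
  lungR <- in_ellipsoid(g, c(75, 0, 100), c(55, 70, 105)) & body
  lung <- (lungL | lungR) & !liver
  act <- array(0, grid)
  n_lung <- sum(lung)
  n_tum <- sum(tumor)
  n_par <- sum(liver & !tumor)
  A <- total_MBq * 1e6
  if (n_lung > 0) act[lung] <- lsf * A / n_lung
  conc <- (1 - lsf) * A / (n_par + tumor_uptake_ratio * n_tum)
  act[liver & !tumor] <- conc
  act[tumor] <- tumor_uptake_ratio * conc
  dens <- array(0.0012, grid)
  dens[body] <- 1.0
  dens[lung] <- 0.26
  lab <- array(0L, grid)
  lab[body] <- 1L
  lab[liver] <- 2L
  lab[tumor] <- 3L
  lab[lung] <- 4L
  b <- new_phantom_bundle(act, dens, lab, voxel_mm, g$origin,
                          tumor_center_mm = tumor_c,
                          liver_center_mm = liver_c)
  b$rotation_center_mm <- mask_centroid(b$labels, lab == 2L | lab == 3L)
  b
}

new_phantom_bundle <- function(act, dens, lab, voxel_mm, origin, ...) {
  b <- list(
    activity = voxel_volume(act, voxel_mm, origin, "activity_Bq"),
    density = voxel_volume(dens, voxel_mm, origin, "density"),
    labels = voxel_volume(lab, voxel_mm, origin, "label"),
    body_contour = body_contour_points(lab > 0, voxel_mm, origin),
    ...)
  class(b) <- "phantom_bundle"
  b
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat("<phantom_bundle>\n  ")
  print(x$activity)
  cat(sprintf("  total activity: %.3f MBq\n",
              total_activity_MBq(x$activity)))
  invisible(x)
}

# transaxial convex outline of the body mask (world mm), used for orbit
# planning: the detector only moves in the transaxial plane
body_contour_points <- function(mask, voxel_mm, origin) {
  m2 <- apply(mask, c(1, 2), any)
  idx <- which(m2, arr.ind = TRUE)
  pts <- cbind(origin[1] + (idx[, 1] - 1) * voxel_mm,
               origin[2] + (idx[, 2] - 1) * voxel_mm)
  hull <- grDevices::chull(pts)
  pts[hull, , drop = FALSE]
}

#' Plan a body-contouring detector orbit
#'
#' The detector rotates around the centroid of the liver (or of all
#' activity when no liver label exists), with the collimator face following
#' the body outline at a 1.0 cm clearance at every angle, i.e. a closed
#' non-circular contour.
#'
#' @param bundle a `phantom_bundle`.
#' @param spec a `collimator_spec` (recorded in the orbit).
#' @param n_views number of views over 360 degrees (default 120).
#' @param time_per_view seconds per view (default 20).
#' @param clearance_mm collimator-face-to-body distance (default 10).
#' @return A `detector_orbit`: per-view angle, face radius and dwell time,
#'   plus the rotation centre.
#' @export
plan_orbit <- function(bundle, spec = NULL, n_views = 120,
                       time_per_view = 20, clearance_mm = 10) {
  stopifnot(n_views >= 2)
  cen <- if (!is.null(bundle$rotation_center_mm)) {
    as.numeric(bundle$rotation_center_mm)
  } else {
    mask_centroid(bundle$activity, bundle$activity$data > 0)
  }
  cxy <- cen[1:2]
  pts <- bundle$body_contour
  ang <- seq(0, 360, length.out = n_views + 1)[seq_len(n_views)]
  rad <- vapply(ang, function(a) {
    n <- c(cos(a * pi / 180), sin(a * pi / 180))
    max((pts[, 1] - cxy[1]) * n[1] + (pts[, 2] - cxy[2]) * n[2]) +
      clearance_mm + 0.5 * bundle$activity$voxel_mm
  }, 0)
  structure(list(
    views = data.frame(view = seq_len(n_views), angle_deg = ang,
                       radius_mm = rad, time_s = time_per_view),
    center = cen, n_views = n_views, spec_kind = if (!is.null(spec)) spec$kind),
    class = "detector_orbit")
}

#' @export
print.detector_orbit <- function(x, ...) {
  cat(sprintf("<detector_orbit> %d views, radius %.1f-%.1f cm, %g s/view\n",
              x$n_views, min(x$views$radius_mm) / 10,
              max(x$views$radius_mm) / 10, x$views$time_s[1]))
  invisible(x)
}
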