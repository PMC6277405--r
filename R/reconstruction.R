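# OSEM reconstruction with resolution recovery, attenuation correction and
# three scatter-correction modes.

#' Reconstruction settings
#'
#' @param n_subsets ordered subsets (default 8; views are interleaved by
#'   angle, view i -> subset (i-1) mod n_subsets).
#' @param n_iterations OSEM iterations (default 10).
#' @param scatter_mode `"mc"` (Monte Carlo-based), `"dew"` (dual energy
#'   window) or `"none"`.
#' @param dew_k scatter-window weight (clinical default 0.5).
#' @param dew_smooth_fwhm_px Gaussian smoothing of the scatter estimate,
#'   FWHM in pixels (default 2).
#' @param mc_histories photon histories per Monte Carlo scatter refresh.
#' @param mc_refresh recompute the MC scatter estimate every iteration
#'   (default TRUE) or once from the initial estimate.
#' @param seed RNG seed for the MC scatter estimate.
#' @param save_every_iteration keep the estimate after each iteration.
#' @export
recon_settings <- function(n_subsets = 8, n_iterations = 10,
                           scatter_mode = c("mc", "dew", "none"),
                           dew_k = 0.5, dew_smooth_fwhm_px = 2,
                           mc_histories = 2e4, mc_refresh = TRUE,
                           seed = NULL, save_every_iteration = FALSE) {
  scatter_mode <- match.arg(scatter_mode)
  stopifnot(n_subsets >= 1, n_iterations >= 1, dew_k >= 0)
  structure(list(n_subsets = n_subsets, n_iterations = n_iterations,
                 scatter_mode = scatter_mode, dew_k = dew_k,
                 dew_smooth_fwhm_px = dew_smooth_fwhm_px,
                 mc_histories = mc_histories, mc_refresh = mc_refresh,
                 seed = seed, save_every_iteration = save_every_iteration),
            class = "recon_settings")
}

#' Forward-project an activity volume (photopeak primaries)
#'
#' The linear system model used inside OSEM: CFD primaries times the
#' photopeak detection probability, for every view.
#'
#' @param act a `voxel_volume` (activity).
#' @param density a `voxel_volume` (density).
#' @param spec,orbit acquisition definition.
#' @param bank optional PSF bank.
#' @return Array `(nu, nv, n_views)`.
#' @export
forward_project <- function(act, density, spec, orbit, bank = NULL) {
  if (is.null(bank)) bank <- make_psf_bank(spec, orbit, act)
  f_pp <- window_detection_prob(140, photopeak_window(),
                                spec$energy_res_fwhm)
  mu <- mu_volume(density)
  meta <- vol_meta_of(act)
  out <- array(0, c(bank$nu, bank$nv, orbit$n_views))
  for (v in seq_len(orbit$n_views))
    out[, , v] <- fp_view(act$data, mu, meta, orbit, v, bank) * f_pp
  out
}

#' Back-project detector data (exact adjoint of [forward_project()])
#'
#' @param y array `(nu, nv, n_views)` (or a matrix for a single view).
#' @param views view indices matching the third dimension of `y`.
#' @inheritParams forward_project
#' @return A 3D array on the activity grid.
#' @export
back_project <- function(y, act, density, spec, orbit, bank = NULL,
                         views = NULL) {
  if (is.null(bank)) bank <- make_psf_bank(spec, orbit, act)
  f_pp <- window_detection_prob(140, photopeak_window(),
                                spec$energy_res_fwhm)
  if (is.matrix(y)) y <- array(y, c(dim(y), 1))
  if (is.null(views)) views <- seq_len(dim(y)[3])
  mu <- mu_volume(density)
  meta <- vol_meta_of(act)
  out <- array(0, dim(act$data))
  for (i in seq_along(views))
    out <- out + bp_view(y[, , i] * f_pp, mu, meta, orbit, views[i], bank)
  out
}

#' Dual-energy-window scatter estimate
#'
#' `k` times the Gaussian-smoothed scatter-window data, per view; constant
#' across iterations.
#'
#' @param ps a `projection_set` containing a `scatter` window.
#' @param k scaling factor (>= 0).
#' @param smooth_fwhm_px Gaussian FWHM in pixels.
#' @return Array `(nu, nv, n_views)`.
#' @export
scatter_estimate_dew <- function(ps, k = 0.5, smooth_fwhm_px = 2) {
  stopifnot(k >= 0)
  sw <- ps$windows$scatter
  if (is.null(sw)) stop("projection set has no scatter window")
  s <- smooth_fwhm_px / 2.3548
  out <- array(0, dim(sw))
  for (v in seq_len(dim(sw)[3]))
    out[, , v] <- k * cpp_gauss2d(sw[, , v], s, s)
  out
}

#' Monte Carlo scatter estimate for the reconstruction loop
#'
#' Forced-detection scatter of the current activity estimate through the
#' known density map, smoothed to suppress Monte Carlo noise.
#'
#' @param est a `voxel_volume` (current activity estimate).
#' @param density a `voxel_volume`.
#' @param spec,orbit acquisition definition.
#' @param settings a [recon_settings()].
#' @param bank optional PSF bank.
#' @return Array `(nu, nv, n_views)` of photopeak scatter means.
#' @export
scatter_estimate_mc <- function(est, density, spec, orbit, settings,
                                bank = NULL) {
  sc <- cfd_scatter(list(activity = est, density = density), spec, orbit,
                    n_histories = settings$mc_histories,
                    windows = list(photopeak = photopeak_window()),
                    activity = est, bank = bank)
  s <- settings$dew_smooth_fwhm_px / 2.3548
  a <- sc$photopeak
  for (v in seq_len(dim(a)[3]))
    a[, , v] <- cpp_gauss2d(a[, , v], s, s)
  a
}

#' OSEM reconstruction
#'
#' Multiplicative ordered-subsets EM with the CFD system model in both the
#' forward and backward projections (attenuation, distance-dependent PSF,
#' Jacobian weighting) and an additive scatter term in the denominator.
#' Voxels outside the union field of view (zero sensitivity) are frozen at
#' their initial value.
#'
#' @param ps a `projection_set` (photopeak window drives the update).
#' @param spec a `collimator_spec` matching the simulation.
#' @param orbit the `detector_orbit`.
#' @param density a `voxel_volume`, co-registered with the target grid.
#' @param settings a [recon_settings()].
#' @param init optional initial `voxel_volume` (default: uniform inside the
#'   body, i.e. where density exceeds 0.1 g/cm3).
#' @return A `recon_result` with the final `estimate` (activity, Bq) and,
#'   if requested, per-iteration estimates.
#' @export
osem <- function(ps, spec, orbit, density, settings = recon_settings(),
                 init = NULL) {
  stopifnot(inherits(ps, "projection_set"))
  meas <- ps$windows$photopeak
  act0 <- voxel_volume(array(1, dim(density$data)), density$voxel_mm,
                       density$origin, "activity_Bq")
  bank <- make_psf_bank(spec, orbit, act0)
  mu <- mu_volume(density)
  meta <- vol_meta_of(density)
  f_pp <- window_detection_prob(140, photopeak_window(),
                                spec$energy_res_fwhm)
  ns <- settings$n_subsets
  subsets <- lapply(seq_len(ns), function(s)
    which((seq_len(orbit$n_views) - 1) %% ns == (s - 1)))
  # subset sensitivity images (backprojection of ones)
  ones <- matrix(1, bank$nu, bank$nv)
  sens <- lapply(subsets, function(vs) {
    out <- array(0, meta$dim)
    for (v in vs) out <- out + bp_view(ones * f_pp, mu, meta, orbit, v, bank)
    out
  })
  sens_tot <- Reduce(`+`, sens)
  mask <- sens_tot > 1e-8 * max(sens_tot)
  body <- density$data > 0.1
  x <- if (is.null(init)) array(as.numeric(body), meta$dim) else init$data
  x[!mask] <- x[!mask]  # frozen outside the union FOV by construction
  if (!is.null(settings$seed)) set.seed(settings$seed)
  scat <- switch(settings$scatter_mode,
    none = NULL,
    dew = scatter_estimate_dew(ps, settings$dew_k,
                               settings$dew_smooth_fwhm_px),
    mc = NULL)  # computed per iteration below
  iterations <- list()
  for (it in seq_len(settings$n_iterations)) {
    if (settings$scatter_mode == "mc" &&
        (settings$mc_refresh || is.null(scat))) {
      est_vol <- voxel_volume(x, density$voxel_mm, density$origin,
                              "activity_Bq")
      scat <- scatter_estimate_mc(est_vol, density, spec, orbit, settings,
                                  bank)
    }
    for (s in seq_len(ns)) {
      num <- array(0, meta$dim)
      for (v in subsets[[s]]) {
        fp <- fp_view(x, mu, meta, orbit, v, bank) * f_pp
        if (!is.null(scat)) fp <- fp + scat[, , v]
        ratio <- meas[, , v] / pmax(fp, 1e-12)
        ratio[meas[, , v] == 0 & fp <= 1e-12] <- 0
        num <- num + bp_view(ratio * f_pp, mu, meta, orbit, v, bank)
      }
      upd <- num / pmax(sens[[s]], 1e-30)
      x[mask] <- x[mask] * upd[mask]
    }
    if (settings$save_every_iteration)
      iterations[[it]] <- voxel_volume(x, density$voxel_mm, density$origin,
                                       "activity_Bq")
  }
  structure(list(
    estimate = voxel_volume(x, density$voxel_mm, density$origin,
                            "activity_Bq"),
    iterations = iterations, settings = settings,
    scatter_term = scat, mask = mask, spec_kind = spec$kind),
    class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("<recon_result> %s scatter, %d it x %d subsets; total %.3f MBq\n",
              x$settings$scatter_mode, x$settings$n_iterations,
              x$settings$n_subsets, total_activity_MBq(x$estimate)))
  invisible(x)
}

#' Grid search for the MSE-optimal dual-energy-window k
#'
#' Reconstructs the projections for each k and returns the k minimizing the
#' mean squared error against the ground-truth phantom over the liver
#' label.  The default grid is centred on the first estimate, the true
#' photopeak-scatter to scatter-window count ratio taken from the
#' simulation components, and is refined once around the minimum.
#'
#' @param ps a `projection_set` (with retained `$components`).
#' @param bundle the ground-truth `phantom_bundle`.
#' @param spec,orbit acquisition definition.
#' @param settings a [recon_settings()]; the scatter mode is forced to
#'   `"dew"`.
#' @param k_grid optional explicit grid of k values.
#' @param refine refine once with half the grid step around the minimum.
#' @return List with `k_opt`, the `table` of (k, mse) pairs, and the
#'   reconstruction at `k_opt`.
#' @export
optimal_k_search <- function(ps, bundle, spec, orbit,
                             settings = recon_settings(scatter_mode = "dew"),
                             k_grid = NULL, refine = TRUE) {
  settings$scatter_mode <- "dew"
  liver <- bundle$labels$data == 2L
  if (!any(liver)) stop("phantom has no liver label")
  truth <- bundle$activity$data
  if (is.null(k_grid)) {
    comp <- ps$components
    if (is.null(comp)) stop("projection set lacks truth components for the ",
                            "initial k estimate; supply k_grid")
    r0 <- sum(comp$scatter_pp) / max(sum(ps$windows$scatter), 1e-12)
    k_grid <- pmax(0.05, r0 + seq(-0.3, 0.3, by = 0.1))
  }
  k_grid <- sort(unique(round(k_grid, 6)))
  run_k <- function(k) {
    s <- settings; s$dew_k <- k
    rec <- osem(ps, spec, orbit, bundle$density, s)
    mean((rec$estimate$data[liver] - truth[liver])^2)
  }
  mse <- vapply(k_grid, run_k, 0)
  if (refine) {
    i <- which.min(mse)
    if (i == 1 || i == length(k_grid))
      stop("k grid argmin lies on the boundary; widen k_grid")
    step <- min(diff(k_grid)) / 2
    extra <- c(k_grid[i] - step, k_grid[i] + step)
    mse_e <- vapply(extra, run_k, 0)
    k_grid <- c(k_grid, extra)
    mse <- c(mse, mse_e)
    o <- order(k_grid)
    k_grid <- k_grid[o]; mse <- mse[o]
  }
  i <- which.min(mse)
  if (i == 1 || i == length(k_grid))
    stop("k grid argmin lies on the boundary; widen k_grid")
  s <- settings; s$dew_k <- k_grid[i]
  list(k_opt = k_grid[i], table = data.frame(k = k_grid, mse = mse),
       recon = osem(ps, spec, orbit, bundle$density, s))
}

#' Enlarge the crystal to emulate an unbounded detector
#'
#' Scales the crystal extent while keeping the focal geometry (and, for the
#' multifocal collimator, the focus zone and the diverging focal points
#' anchored at the original crystal edge), so projections are free of
#' truncation by the physical camera size.
#'
#' @param spec a `collimator_spec`.
#' @param factor linear enlargement factor (default 3).
#' @export
expand_crystal <- function(spec, factor = 3) {
  stopifnot(factor >= 1)
  if (is.null(spec$anchor_mm)) spec$anchor_mm <- spec$crystal_mm
  spec$crystal_mm <- spec$crystal_mm * factor
  spec
}

#' Reconstruct without camera-size truncation
#'
#' Re-simulates the phantom with an enlarged (effectively unbounded)
#' crystal and reconstructs with the same settings: the truncation-free
#' reference for truncation studies.
#'
#' @param bundle a `phantom_bundle`.
#' @param spec,orbit acquisition definition (the physical spec).
#' @param settings a [recon_settings()].
#' @param n_scatter_histories scatter budget for the simulation.
#' @param noise_seed Poisson seed (NULL for noiseless).
#' @param factor crystal enlargement factor.
#' @export
reconstruct_untruncated <- function(bundle, spec, orbit,
                                    settings = recon_settings(),
                                    n_scatter_histories = 2e4,
                                    noise_seed = 1, factor = 3) {
  spec_inf <- expand_crystal(spec, factor)
  ps <- project(bundle, spec_inf, orbit, n_scatter_histories,
                seed = settings$seed)
  if (!is.null(noise_seed)) ps <- add_poisson(ps, noise_seed)
  osem(ps, spec_inf, orbit, bundle$density, settings)
}

#' @rdname tidy_recon
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Tidy a reconstruction result
#'
#' Per-iteration summary (requires `save_every_iteration = TRUE`):
#' iteration index and total activity; if a phantom bundle is supplied,
#' tumor-VOI activity recovery per iteration.
#'
#' @param x a `recon_result`.
#' @param bundle optional `phantom_bundle` for recovery.
#' @param ... unused.
#' @name tidy_recon
#' @export
tidy.recon_result <- function(x, bundle = NULL, ...) {
  its <- if (length(x$iterations)) x$iterations else list(x$estimate)
  df <- data.frame(iteration = seq_along(its),
                   total_MBq = vapply(its, total_activity_MBq, 0))
  if (!is.null(bundle)) {
    voi <- erode_mask(bundle$labels$data == 3L)
    df$tumor_recovery_pct <- vapply(its, function(e)
      100 * sum(e$data[voi]) / sum(bundle$activity$data[voi]), 0)
  }
  df
}
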