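# Evaluation metrics: VOIs, activity recovery, noise, profiles, truncation
# and equal-noise scan-time analysis.

# one-pass 6-connected erosion of a logical 3D mask
erode_mask <- function(mask) {
  d <- dim(mask)
  shift <- function(m, ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (by > 0) { idx_dst[[ax]] <- seq(1 + by, d[ax]); idx_src[[ax]] <- seq(1, d[ax] - by) }
    else       { idx_dst[[ax]] <- seq(1, d[ax] + by); idx_src[[ax]] <- seq(1 - by, d[ax]) }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  out <- mask
  for (ax in 1:3)
    for (by in c(-1, 1))
      out <- out & shift(mask, ax, by)
  out
}

#' Volumes of interest for the phantom study
#'
#' Tumor VOI: the tumor label eroded by one pixel (6-connected, one pass)
#' to reduce partial-volume effects.  Background-liver VOI: the liver
#' region inside the cone-beam (50 cm) high-sensitivity zone (geometric
#' sensitivity above its in-liver median) and inside its >50%-of-views
#' field of view, minus the tumor VOI.  Lung VOI: likewise for the lung.
#'
#' @param bundle a `phantom_bundle` from [make_liver_phantom()].
#' @param orbit the acquisition orbit.
#' @param spec50 the cone-beam 50 cm `collimator_spec` defining the hot
#'   region (default `make_collimator("conebeam", 50)`).
#' @return List of logical masks `tumor`, `background_liver`, `lung`.
#' @export
make_vois <- function(bundle, orbit,
                      spec50 = make_collimator("conebeam", 50)) {
  lab <- bundle$labels$data
  tumor <- erode_mask(lab == 3L)
  smap <- sensitivity_map(spec50, orbit, bundle$labels)$data
  fov <- fov_fraction_map(spec50, orbit, bundle$labels)$data > 0.5
  liver <- lab %in% c(2L, 3L)
  dim(liver) <- dim(lab)
  hot <- smap > quantile(smap[liver], 0.5)
  bg <- liver & hot & fov & !tumor & !(lab == 3L)
  lung <- lab == 4L
  lung_hot <- lung & fov & smap > 0
  list(tumor = tumor, background_liver = bg, lung = lung_hot)
}

#' Activity recovery in a VOI
#'
#' `100 * sum(recon in VOI) / sum(phantom in VOI)`, in percent.
#'
#' @param recon a `recon_result` or `voxel_volume`.
#' @param phantom the ground-truth activity `voxel_volume` (or a
#'   `phantom_bundle`).
#' @param voi logical mask on the same grid.
#' @export
activity_recovery <- function(recon, phantom, voi) {
  r <- if (inherits(recon, "recon_result")) recon$estimate else recon
  p <- if (inherits(phantom, "phantom_bundle")) phantom$activity else phantom
  if (!any(voi)) stop("empty VOI")
  100 * sum(r$data[voi]) / sum(p$data[voi])
}

#' Ensemble noise level in a VOI
#'
#' Across-realization per-voxel standard deviation, averaged over the VOI
#' and normalized to the VOI mean activity.  With `method = "spatial"` the
#' in-VOI spatial SD of each realization is averaged instead.
#'
#' @param recons list of `recon_result`s or `voxel_volume`s (>= 2 for the
#'   ensemble method).
#' @param voi logical mask.
#' @param method `"ensemble"` (default) or `"spatial"`.
#' @export
noise_level <- function(recons, voi, method = c("ensemble", "spatial")) {
  method <- match.arg(method)
  vols <- lapply(recons, function(r)
    if (inherits(r, "recon_result")) r$estimate$data else r$data)
  if (!any(voi)) stop("empty VOI")
  m <- vapply(vols, function(v) mean(v[voi]), 0)
  if (method == "spatial")
    return(mean(vapply(vols, function(v) sd(v[voi]), 0)) / mean(m))
  if (length(vols) < 2) stop("ensemble noise needs >= 2 realizations")
  vals <- sapply(vols, function(v) v[voi])  # nvox x nreal
  mean(apply(vals, 1, sd)) / mean(m)
}

#' Activity recovery profile along a line
#'
#' 1D profile through the volume, normalized to its own maximum, paired
#' with the phantom profile when given.
#'
#' @param recon a `recon_result` or `voxel_volume`.
#' @param center_mm world point the line passes through (e.g. the tumor
#'   centre).
#' @param axis 1, 2 or 3 (world x, y, z).
#' @param phantom optional ground-truth `voxel_volume`.
#' @return data.frame with `position_mm`, `profile` and optionally
#'   `phantom`.
#' @export
recovery_profile <- function(recon, center_mm, axis = 1, phantom = NULL) {
  r <- if (inherits(recon, "recon_result")) recon$estimate else recon
  idx <- round((center_mm - r$origin) / r$voxel_mm) + 1
  d <- dim(r$data)
  if (any(idx < 1) || any(idx > d)) stop("line outside grid")
  sel <- as.list(idx)
  sel[[axis]] <- seq_len(d[axis])
  line <- do.call(`[`, c(list(r$data), sel))
  pos <- r$origin[axis] + (seq_len(d[axis]) - 1) * r$voxel_mm
  out <- data.frame(position_mm = pos, profile = line / max(line))
  if (!is.null(phantom)) {
    p <- if (inherits(phantom, "phantom_bundle")) phantom$activity else phantom
    pl <- do.call(`[`, c(list(p$data), sel))
    out$phantom <- pl / max(pl)
  }
  class(out) <- c("recovery_profile", class(out))
  out
}

#' Truncation-free volume fraction of an organ
#'
#' Percentage of organ voxels seen by more than half of the views.
#'
#' @param fov_map a `voxel_volume` from [fov_fraction_map()].
#' @param organ_mask logical mask.
#' @export
truncation_fraction <- function(fov_map, organ_mask) {
  if (!any(organ_mask)) stop("empty organ mask")
  100 * mean(fov_map$data[organ_mask] > 0.5)
}

#' Build a noise-versus-time metric curve
#'
#' @param times_s view durations.
#' @param noise noise level per duration.
#' @param collimator label.
#' @param sd optional across-realization SD of the noise estimate.
#' @param n_realizations number of realizations behind each point.
#' @export
metric_curve <- function(times_s, noise, collimator = "collimator",
                         sd = NA_real_, n_realizations = NA_integer_) {
  df <- data.frame(collimator = collimator, time_s = times_s, noise = noise,
                   sd = sd, n_realizations = n_realizations)
  class(df) <- c("metric_curve", class(df))
  df
}

#' Equal-noise scan time
#'
#' Interpolates a focusing collimator's noise-versus-time curve (monotone
#' piecewise-cubic) to the time at which it reaches the reference
#' collimator's noise at the reference view duration.
#'
#' @param curves a data.frame (rows from [metric_curve()]) with columns
#'   `collimator`, `time_s`, `noise`.
#' @param reference reference collimator label (default `"parallel"`).
#' @param reference_time_s reference duration (default 20).
#' @return data.frame with `collimator`, `time_s` (equal-noise seconds per
#'   view) and `percent_of_reference`.
#' @export
equal_noise_time <- function(curves, reference = "parallel",
                             reference_time_s = 20) {
  ref <- curves[curves$collimator == reference, ]
  if (!nrow(ref)) stop("reference collimator not in curves")
  fr <- splinefun(ref$time_s, ref$noise, method = "hyman")
  target <- fr(reference_time_s)
  others <- setdiff(unique(curves$collimator), reference)
  res <- lapply(others, function(cl) {
    cc <- curves[curves$collimator == cl, ]
    cc <- cc[order(cc$time_s), ]
    fc <- splinefun(cc$time_s, cc$noise, method = "hyman")
    rng <- range(cc$time_s)
    if ((fc(rng[1]) - target) * (fc(rng[2]) - target) > 0) {
      if (all(cc$noise > target))
        stop("reference noise outside curve range for ", cl)
      t_eq <- rng[1]  # already quieter than the reference at the shortest time
    } else {
      t_eq <- uniroot(function(t) fc(t) - target, rng)$root
    }
    data.frame(collimator = cl, time_s = t_eq,
               percent_of_reference = 100 * t_eq / reference_time_s)
  })
  out <- do.call(rbind, res)
  out <- rbind(out, data.frame(collimator = reference,
                               time_s = reference_time_s,
                               percent_of_reference = 100))
  out[order(out$time_s), ]
}
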