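# Plotting helpers.

#' Display one projection view
#'
#' @param ps a `projection_set`.
#' @param view view index.
#' @param window window name (default `"photopeak"`).
#' @param ... passed to [graphics::image()].
#' @export
plot_projection <- function(ps, view = 1, window = "photopeak", ...) {
  img <- ps$windows[[window]][, , view]
  graphics::image(img, useRaster = TRUE, asp = ncol(img) / nrow(img),
                  col = grDevices::hcl.colors(64, "inferno"),
                  main = sprintf("%s, view %d", window, view), ...)
  invisible(img)
}

#' Display a transaxial/coronal/sagittal slice of a volume
#'
#' @param vol a `voxel_volume` (or `recon_result`).
#' @param slice slice index (default: middle).
#' @param axis axis perpendicular to the slice (default 3, transaxial).
#' @param ... passed to [graphics::image()].
#' @export
plot_volume_slice <- function(vol, slice = NULL, axis = 3, ...) {
  if (inherits(vol, "recon_result")) vol <- vol$estimate
  d <- dim(vol$data)
  if (is.null(slice)) slice <- ceiling(d[axis] / 2)
  sel <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  sel[[axis]] <- slice
  img <- do.call(`[`, c(list(vol$data), sel))
  graphics::image(img, useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "inferno"), ...)
  invisible(img)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot noise-versus-time curves
#'
#' @param object a data.frame of [metric_curve()] rows.
#' @param ... unused.
#' @export
autoplot.metric_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time_s, y = .data$noise,
                               colour = .data$collimator)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time per view (s)", y = "normalized noise level") +
    ggplot2::theme_minimal()
}

#' Plot a recovery profile against the phantom truth
#' @param object a `recovery_profile` data.frame.
#' @param ... unused.
#' @export
autoplot.recovery_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$position_mm)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$profile,
                                    colour = "reconstruction")) +
    ggplot2::labs(x = "position (mm)", y = "normalized activity") +
    ggplot2::theme_minimal()
  if (!is.null(object$phantom))
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$phantom,
                                             colour = "phantom"))
  p
}

#' @importFrom ggplot2 .data
NULL
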