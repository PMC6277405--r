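#' Voxel volume
#'
#' A 3D scalar grid with isotropic voxel size and world origin.  The world
#' position of the centre of voxel `[1, 1, 1]` is `origin` (mm); the first
#' array index runs along world x (fastest), then y, then z (the patient
#' axis).  `semantics` records what the values mean.
#'
#' @param data 3D numeric array.
#' @param voxel_mm isotropic voxel size in mm.
#' @param origin world mm of the centre of voxel `[1,1,1]`; default centres
#'   the grid on the world origin.
#' @param semantics one of `"activity_Bq"`, `"density"`, `"label"`,
#'   `"fraction"`, `"mu_cm"`.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, voxel_mm,
                         origin = NULL,
                         semantics = c("activity_Bq", "density", "label",
                                       "fraction", "mu_cm")) {
  semantics <- match.arg(semantics)
  stopifnot(length(dim(data)) == 3, voxel_mm > 0)
  if (is.null(origin)) origin <- -(dim(data) - 1) / 2 * voxel_mm
  if (semantics == "activity_Bq" && any(data < 0))
    stop("activity must be non-negative everywhere")
  structure(list(data = data, voxel_mm = voxel_mm, origin = origin,
                 semantics = semantics),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d @ %.3g mm (%s)\n",
              d[1], d[2], d[3], x$voxel_mm, x$semantics))
  cat(sprintf("  origin (mm): %.1f %.1f %.1f | sum = %.4g\n",
              x$origin[1], x$origin[2], x$origin[3], sum(x$data)))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

# world-mm coordinates of voxel centres along each axis
axis_coords <- function(vol) {
  d <- dim(vol$data)
  lapply(1:3, function(a) vol$origin[a] + (seq_len(d[a]) - 1) * vol$voxel_mm)
}

# centroid (world mm) of a logical mask
mask_centroid <- function(vol, mask) {
  idx <- which(mask, arr.ind = TRUE)
  cen <- colMeans(idx) - 1
  vol$origin + cen * vol$voxel_mm
}

#' Total activity of a volume in MBq
#' @param vol a `voxel_volume` with activity semantics.
#' @export
total_activity_MBq <- function(vol) {
  stopifnot(vol$semantics == "activity_Bq")
  sum(vol$data) / 1e6
}
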