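# Shared small fixtures, built in code and memoized per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# random soft-tissue blob with activity, for operator-level tests
small_bundle <- function(seed = 7, grid = c(24, 24, 20), vox = 12) {
  memo(paste0("blob", seed, grid[1]), {
    set.seed(seed)
    dens <- array(0, grid); dens[5:20, 5:20, 4:16] <- 1
    act <- array(0, grid)
    act[8:16, 8:16, 6:14] <- runif(9 * 9 * 9)
    org <- -(grid - 1) / 2 * vox
    b <- list(activity = voxel_volume(act, vox, semantics = "activity_Bq"),
              density = voxel_volume(dens, vox, semantics = "density"),
              labels = voxel_volume(array(0L, grid), vox,
                                    semantics = "label"))
    b$body_contour <- spectsim:::body_contour_points(dens > 0, vox, org)
    b$rotation_center_mm <- c(0, 0, 0)
    class(b) <- "phantom_bundle"
    b
  })
}

# point source bundle in near-vacuum at the grid centre
point_bundle <- function(grid = c(33, 33, 33), vox = 10, A = 1e6) {
  memo("point", {
    act <- array(0, grid)
    act[(grid[1] + 1) / 2, (grid[2] + 1) / 2, (grid[3] + 1) / 2] <- A
    b <- list(activity = voxel_volume(act, vox, semantics = "activity_Bq"),
              density = voxel_volume(array(0, grid), vox,
                                     semantics = "density"),
              labels = voxel_volume(array(0L, grid), vox,
                                    semantics = "label"))
    b$body_contour <- cbind(c(-50, 50, 50, -50), c(-50, -50, 50, 50))
    b$rotation_center_mm <- c(0, 0, 0)
    class(b) <- "phantom_bundle"
    b
  })
}

# fixed-radius single-view orbit for geometry tests
fixed_orbit <- function(radius_mm = 250, n_views = 1, time_s = 1,
                        center = c(0, 0, 0)) {
  ang <- seq(0, 360, length.out = n_views + 1)[seq_len(n_views)]
  structure(list(views = data.frame(view = seq_len(n_views),
                                    angle_deg = ang,
                                    radius_mm = radius_mm,
                                    time_s = time_s),
                 center = center, n_views = n_views),
            class = "detector_orbit")
}

small_liver <- function() memo("liver48",
  make_liver_phantom(grid = c(48, 48, 34), voxel_mm = 12.5))

small_nema <- function() memo("nema32",
  make_nema_phantom(grid = c(32, 32, 32), voxel_mm = 10, total_MBq = 50))
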