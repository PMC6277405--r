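test_that("LEHR defaults and the four standard configurations are exact", {
  cb <- make_collimator("conebeam", 50)
  expect_equal(cb$hole_length_mm, 24.05)
  expect_equal(cb$hole_diameter_mm, 1.11)
  expect_equal(cb$septal_mm, 0.16)
  expect_equal(cb$crystal_mm, c(533, 387))
  expect_equal(cb$focal_mm, 500)

  par <- make_collimator("parallel")
  expect_true(is.infinite(par$focal_mm))

  mf <- make_collimator("multifocal", 50)
  expect_equal(mf$focus_mm, c(267, 194))
  # focusing zone covers half of the crystal extent along each axis
  expect_equal(mf$focus_mm / mf$crystal_mm, c(0.5009, 0.5013),
               tolerance = 1e-3)

  expect_error(make_collimator("conebeam"), "focal length")
  expect_error(make_collimator("conebeam", -10), "positive")
  expect_error(make_collimator("parallel", hole_diameter_mm = -1))
})

test_that("magnification follows similar triangles and is monotone", {
  cb <- make_collimator("conebeam", 50)
  # ray construction oracle: line from focal point (0, F) through (x, z)
  # crosses the detector plane z = 0 at u = x * F / (F - z)
  ray_mag <- function(F, z) {
    x <- 37
    u <- x + (0 - z) * (x - 0) / (z - F)
    u / x
  }
  expect_equal(unname(magnification(cb, z_mm = 250)["x"]), ray_mag(500, 250))
  expect_equal(unname(magnification(cb, z_mm = 250)["x"]), 2)
  expect_equal(unname(magnification(cb, z_mm = 0)["x"]), 1)
  expect_equal(unname(magnification(make_collimator("parallel"),
                                    z_mm = 321)["x"]), 1, tolerance = 1e-9)
  # continuity / monotonicity in z
  z <- seq(0, 450, by = 10)
  m <- vapply(z, function(zz) magnification(cb, z_mm = zz)[["x"]], 0)
  expect_true(all(diff(m) > 0))
  expect_error(magnification(cb, z_mm = 500), "focal")

  mf <- make_collimator("multifocal", 50)
  regs <- collimator_regions(mf)
  div <- which(vapply(regs, `[[`, "", "type") == "diverge_x_diverge_y")[1]
  md <- magnification(mf, div, 250)
  expect_true(all(md < 1) && all(md > 0))
})

test_that("jacobian sensitivity is 1/cos^2 of the hole inclination", {
  cb <- make_collimator("conebeam", 50)
  expect_equal(jacobian_sensitivity(cb, 0, 0), 1)
  expect_equal(jacobian_sensitivity(cb, 100, 0),
               1 / cos(atan(100 / 500))^2)
  expect_equal(jacobian_sensitivity(cb, 100, 0), 1.04)
  par <- make_collimator("parallel")
  expect_equal(jacobian_sensitivity(par, 150, 80), 1, tolerance = 1e-9)
  # always >= 1, equal only on the focal axis
  u <- seq(-250, 250, by = 50)
  J <- vapply(u, function(uu) jacobian_sensitivity(cb, uu, 0), 0)
  expect_true(all(J >= 1))
  expect_equal(sum(J == 1), 1)
})

test_that("psf kernels normalize to the region sensitivity and broaden with depth", {
  cb <- make_collimator("conebeam", 50)
  k0 <- psf_kernel(cb, z_mm = 0, pitch_mm = 4.7)
  expect_equal(sum(k0$kernel), k0$sensitivity, tolerance = 1e-6)
  # z = 0: quadrature of the geometric response at the face and the
  # intrinsic camera resolution
  expect_equal(unname(k0$fwhm_mm[1]),
               sqrt(geometric_fwhm(cb, 0)^2 + 3.8^2), tolerance = 1e-9)
  # FWHM monotone non-decreasing in z for every collimator
  for (spec in list(cb, make_collimator("parallel"),
                    make_collimator("multifocal", 50))) {
    f <- vapply(seq(0, 400, by = 50), function(z)
      psf_kernel(spec, z_mm = z, pitch_mm = 4.7)$fwhm_mm[1], 0)
    expect_true(all(diff(f) >= 0))
  }
  # with no intrinsic blur the geometric response grows linearly in z
  nb <- make_collimator("conebeam", 50, intrinsic_fwhm_mm = 0)
  z <- c(100, 200, 400)
  fg <- geometric_fwhm(nb, z)
  expect_equal(fg[3] - fg[2], 2 * (fg[2] - fg[1]), tolerance = 1e-9)
})

test_that("multifocal regions partition the detector with a 2-pixel blend", {
  mf <- make_collimator("multifocal", 50)
  rm <- region_map(mf, 113, 82, 4.7)
  expect_equal(sort(unique(as.vector(rm$region_id))), 1:9)
  w <- spectsim:::region_weights(mf, 113, 82, 4.7)
  tot <- Reduce(`+`, w)
  expect_equal(max(abs(tot - 1)), 0, tolerance = 1e-9)
  # blend band: exactly two pixel columns around each x boundary
  u <- (seq_len(113) - 57) * 4.7
  inner <- w[[5]]  # focus_x_focus_y
  vmid <- 41      # inside the focus_y zone
  col <- inner[, vmid]
  partial <- which(col > 1e-9 & col < 1 - 1e-9)
  b <- 267 / 2
  expect_true(length(partial) > 0)
  expect_true(all(abs(abs(u[partial]) - b) <= 2 * 4.7))

  # single-region collimators: one region, no blend
  rp <- region_map(make_collimator("parallel"), 113, 82, 4.7)
  expect_equal(unique(as.vector(rp$region_id)), 1)
  expect_false(any(rp$blend_mask))
})

test_that("multifocal field of view equals the parallel-hole field of view", {
  mf <- make_collimator("multifocal", 50)
  zx <- spectsim:::axis_zones(mf, 1)
  # derived diverging focal length makes the outermost hole parallel:
  # the object-space edge of the FOV is the crystal edge at every depth
  W2 <- mf$crystal_mm[1] / 2
  for (d in c(0, 100, 250, 400)) {
    Fd <- zx[3, "F"]; e <- zx[3, "e"]
    edge_obj <- e + (W2 - e) * (Fd - d) / Fd
    expect_equal(unname(edge_obj), W2, tolerance = 1e-9)
  }
  # and numerically: the FOV fraction maps agree voxel-by-voxel wherever
  # the converging zone resolves (depth below ~95% of the focal length)
  b <- small_bundle()
  orbit <- fixed_orbit(250, n_views = 8)
  fmf <- fov_fraction_map(mf, orbit, b$activity)
  fpar <- fov_fraction_map(make_collimator("parallel"), orbit, b$activity)
  expect_equal(fmf$data, fpar$data, tolerance = 1e-12)
})

test_that("fov fraction map flags truncation where geometry dictates", {
  b <- point_bundle()
  orbit <- fixed_orbit(250, n_views = 8)
  # voxel at the rotation centre of a cone-beam 50 with orbit radius < F
  cb <- make_collimator("conebeam", 50)
  f <- fov_fraction_map(cb, orbit, b$activity)
  cen <- (dim(b$activity$data) + 1) / 2
  expect_equal(f$data[cen[1], cen[2], cen[3]], 1)
  # parallel collimator: binary visibility for a grid under the crystal
  fp <- fov_fraction_map(make_collimator("parallel"), orbit, b$activity)
  expect_true(all(fp$data %in% c(0, 1)))
  # shrinking the crystal monotonically decreases coverage
  liver <- small_liver()
  lab <- liver$labels$data
  orb <- plan_orbit(liver, cb, n_views = 16, time_per_view = 20)
  f1 <- truncation_fraction(fov_fraction_map(cb, orb, liver$labels),
                            lab == 2L | lab == 3L)
  cb_small <- make_collimator("conebeam", 50, crystal_mm = c(400, 290))
  f2 <- truncation_fraction(fov_fraction_map(cb_small, orb, liver$labels),
                            lab == 2L | lab == 3L)
  cb_tiny <- make_collimator("conebeam", 50, crystal_mm = c(260, 190))
  f3 <- truncation_fraction(fov_fraction_map(cb_tiny, orb, liver$labels),
                            lab == 2L | lab == 3L)
  expect_true(f1 >= f2 && f2 >= f3 && f3 < f1)
})

test_that("liver phantom coverage: cone-beam 50 sees more liver than lung", {
  liver <- small_liver()
  lab <- liver$labels$data
  cb <- make_collimator("conebeam", 50)
  orb <- plan_orbit(liver, cb, n_views = 16, time_per_view = 20)
  fov <- fov_fraction_map(cb, orb, liver$labels)
  lv <- truncation_fraction(fov, lab == 2L | lab == 3L)
  lu <- truncation_fraction(fov, lab == 4L)
  expect_gt(lv, lu)
  expect_gt(lv, 75)
  # the caudal liver leaves the FOV in a sizeable minority of views
  # (partial coverage), while the parallel collimator sees it always
  expect_lt(min(fov$data[lab == 2L | lab == 3L]), 0.8)
  par <- make_collimator("parallel")
  fovp <- fov_fraction_map(par, plan_orbit(liver, par, 16, 20),
                           liver$labels)
  expect_equal(min(fovp$data[lab == 2L | lab == 3L]), 1)
})

test_that("collimator spec round-trips through its text format", {
  mf <- make_collimator("multifocal", 50)
  path <- tempfile(fileext = ".txt")
  write_collimator(mf, path)
  back <- read_collimator(path)
  expect_equal(back$hole_diameter_mm, mf$hole_diameter_mm)
  expect_equal(back$crystal_mm, mf$crystal_mm)
  expect_equal(back$diverge_focal_mm, mf$diverge_focal_mm, tolerance = 1e-9)
  expect_equal(back$kind, "multifocal")
})
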