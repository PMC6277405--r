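test_that("rotate+warp is the identity for a parallel collimator at 0 degrees", {
  b <- point_bundle()  # delta at the grid centre, 10 mm voxels
  orbit <- fixed_orbit(255, n_views = 1)  # aligns depth planes with voxels
  par <- make_collimator("parallel")
  w <- rotate_warp(b$activity, orbit, 1, par)
  # the delta must reappear as a single unsmeared sample
  expect_equal(max(w), 1e6, tolerance = 1e-6)
  expect_equal(sum(w), 1e6, tolerance = 1e-6)
  pk <- unname(which(w == max(w), arr.ind = TRUE)[1, ])
  # centre voxel is at world origin: detector coords (0,0), depth 255
  expect_equal(pk[3], 26)        # d = 255 = (26 - 0.5) * 10
  u <- (pk[1] - (dim(w)[1] + 1) / 2) * 10
  v <- (pk[2] - (dim(w)[2] + 1) / 2) * 10
  expect_equal(unname(c(u, v)), c(0, 0))
})

test_that("warped point source lands at the ray-traced detector position", {
  grid <- c(24, 24, 20); vox <- 12
  spec <- make_collimator("conebeam", 50)
  orbit <- fixed_orbit(250, n_views = 1)
  act <- array(0, grid); act[13, 21, 11] <- 1
  av <- voxel_volume(act, vox, semantics = "activity_Bq")
  w <- rotate_warp(av, orbit, 1, spec)
  nu <- dim(w)[1]
  uu <- (seq_len(nu) - (nu + 1) / 2) * vox
  prof_u <- apply(w, 1, sum)
  got_u <- sum(uu * prof_u) / sum(prof_u)
  # voxel [13,21,11] world: x = 6, y = 102, z = -18; view 0 deg:
  # depth = 250 - 6 = 244, transverse 102 -> M = 500/(500-244)
  # interpolation spreads across two planes; ray-trace both and average
  # with the trilinear weights (0.2 / 0.8 for depth 244 on a 10*k+4 grid)
  d_lo <- 234; d_hi <- 246
  w_hi <- (244 - d_lo) / 12
  want <- 102 * (w_hi * 500 / (500 - d_hi) + (1 - w_hi) * 500 / (500 - d_lo))
  expect_lt(abs(got_u - want), vox)  # within one pixel
})

test_that("point-source projections match the analytic sensitivity", {
  b <- point_bundle()  # 1 MBq in near-vacuum
  par <- make_collimator("parallel")
  orbit <- fixed_orbit(250, n_views = 1, time_s = 4)
  P <- cfd_primary(b, par, orbit, 1)
  g <- collimator_sensitivity(par)
  pdet <- 1 - exp(-par$crystal_mu_cm * 0.1 * par$crystal_thick_mm)
  expect_equal(sum(P), 1e6 * 4 * g * pdet, tolerance = 0.01)
  # off-centre point: the Jacobian factor scales the total
  b2 <- point_bundle()
  act <- array(0, dim(b2$activity$data)); act[17, 27, 17] <- 1e6
  b2$activity <- voxel_volume(act, 10, semantics = "activity_Bq")
  cb <- make_collimator("conebeam", 50)
  P2 <- cfd_primary(b2, cb, orbit, 1)
  set.seed(21)
  o <- mc_oracle_project(c(0, 100, 0), cb, orbit, 1, n_photons = 5e5,
                         vacuum = TRUE, pitch_mm = 10)
  f140 <- window_detection_prob(140, photopeak_window(), cb$energy_res_fwhm)
  # fast vs analog oracle: total counts within 2% (the projection already
  # carries the 4 s dwell; the oracle image is per decay)
  expect_equal(sum(P2) * f140, sum(o$photopeak) * 1e6 * 4,
               tolerance = 0.02)
  # and the PSF centroids within one pixel
  uu <- (seq_len(nrow(P2)) - (nrow(P2) + 1) / 2) * 10
  cf <- sum(uu * rowSums(P2)) / sum(P2)
  co <- sum(uu * rowSums(o$photopeak)) / sum(o$photopeak)
  expect_lt(abs(cf - co), 10)
})

test_that("oracle sensitivity for parallel holes matches the closed form", {
  par <- make_collimator("parallel")
  orbit <- fixed_orbit(250, n_views = 1)
  set.seed(4)
  o <- mc_oracle_project(c(0, 0, 0), par, orbit, 1, n_photons = 4e5,
                         vacuum = TRUE, pitch_mm = 10)
  pdet <- 1 - exp(-par$crystal_mu_cm * 0.1 * par$crystal_thick_mm)
  f140 <- window_detection_prob(140, photopeak_window(), par$energy_res_fwhm)
  want <- collimator_sensitivity(par) * pdet * f140
  expect_equal(sum(o$photopeak), want, tolerance = 0.05)
  # on-axis PSF is symmetric
  uu <- (seq_len(o$nu) - (o$nu + 1) / 2) * 10
  cen <- sum(uu * rowSums(o$photopeak)) / sum(o$photopeak)
  expect_lt(abs(cen), 2)
})

test_that("primary projection is linear in the activity", {
  b <- small_bundle()
  spec <- make_collimator("conebeam", 50)
  orbit <- plan_orbit(b, spec, n_views = 2, time_per_view = 5)
  A <- b$activity
  set.seed(3)
  Bd <- array(runif(length(A$data)), dim(A$data))
  B <- voxel_volume(Bd, A$voxel_mm, A$origin, "activity_Bq")
  mk <- function(vol) {
    bb <- b; bb$activity <- vol; class(bb) <- "phantom_bundle"; bb
  }
  P_A <- cfd_primary(mk(A), spec, orbit, 1)
  P_B <- cfd_primary(mk(B), spec, orbit, 1)
  comb <- voxel_volume(2 * A$data + 0.5 * Bd, A$voxel_mm, A$origin,
                       "activity_Bq")
  P_C <- cfd_primary(mk(comb), spec, orbit, 1)
  expect_equal(P_C, 2 * P_A + 0.5 * P_B, tolerance = 1e-10)
  # zero activity projects to zero
  z <- voxel_volume(array(0, dim(A$data)), A$voxel_mm, A$origin,
                    "activity_Bq")
  expect_equal(sum(cfd_primary(mk(z), spec, orbit, 1)), 0)
  # doubling the dwell time doubles every pixel
  orbit2 <- orbit; orbit2$views$time_s <- orbit$views$time_s * 2
  expect_equal(cfd_primary(mk(A), spec, orbit2, 1), 2 * P_A,
               tolerance = 1e-12)
})

test_that("scatter projector behaves physically", {
  b <- small_bundle()
  spec <- make_collimator("conebeam", 50)
  orbit <- plan_orbit(b, spec, n_views = 2, time_per_view = 5)
  # vacuum density -> zero scatter in all windows
  bv <- b
  bv$density <- voxel_volume(array(0, dim(b$density$data)),
                             b$density$voxel_mm, b$density$origin,
                             "density")
  class(bv) <- "phantom_bundle"
  set.seed(1)
  sc <- cfd_scatter(bv, spec, orbit, n_histories = 2000)
  expect_equal(sum(sc$photopeak) + sum(sc$scatter), 0)
  # Monte Carlo convergence: quadrupling the histories halves the spread
  est <- function(n, seeds) vapply(seeds, function(s) {
    set.seed(s)
    sum(cfd_scatter(b, spec, orbit, n_histories = n)$photopeak)
  }, 0)
  e1 <- est(1500, 1:8)
  e4 <- est(6000, 1:8)
  expect_equal(mean(e4), mean(e1), tolerance = 0.2)
  ratio <- sd(e1) / sd(e4)
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 3.5)
  # scatter window means add on top of primary leakage only
  ps_off <- project(b, spec, orbit, n_scatter_histories = 0)
  set.seed(2)
  ps_on <- project(b, spec, orbit, n_scatter_histories = 5000)
  expect_equal(ps_on$windows$photopeak - ps_on$components$scatter_pp,
               ps_off$windows$photopeak, tolerance = 1e-9)
})

test_that("Poisson noise is reproducible and unbiased", {
  b <- small_bundle()
  spec <- make_collimator("parallel")
  orbit <- plan_orbit(b, spec, n_views = 2, time_per_view = 5)
  ps <- project(b, spec, orbit, n_scatter_histories = 0)
  c1 <- add_poisson(ps, seed = 123)
  c2 <- add_poisson(ps, seed = 123)
  expect_identical(c1$windows, c2$windows)
  expect_true(all(c1$windows$photopeak == round(c1$windows$photopeak)))
  expect_equal(c1$kind, "counts")
  # zero-mean pixels never produce counts
  expect_true(all(c1$windows$photopeak[ps$windows$photopeak == 0] == 0))
  # aggregate counts agree with the mean within 3 sigma
  m <- sum(ps$windows$photopeak)
  expect_lt(abs(sum(c1$windows$photopeak) - m), 3 * sqrt(m) + 1)
  # mean-kind guard
  expect_error(add_poisson(c1), "mean")
})

test_that("liver-phantom photopeak counts rank cone50 > multifocal > cone100 > parallel", {
  ph <- small_liver()
  totals <- vapply(list(make_collimator("conebeam", 50),
                        make_collimator("multifocal", 50),
                        make_collimator("conebeam", 100),
                        make_collimator("parallel")), function(spec) {
    orbit <- plan_orbit(ph, spec, n_views = 4, time_per_view = 20)
    set.seed(17)
    ps <- project(ph, spec, orbit, n_scatter_histories = 3e4, seed = 17)
    sum(ps$windows$photopeak)
  }, 0)
  expect_true(all(diff(totals) < 0))
})
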