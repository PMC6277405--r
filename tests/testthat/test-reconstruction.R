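test_that("forward and backward projectors are exact adjoints", {
  b <- small_bundle()
  for (spec in list(make_collimator("parallel"),
                    make_collimator("conebeam", 50),
                    make_collimator("conebeam", 100),
                    make_collimator("multifocal", 50))) {
    orbit <- plan_orbit(b, spec, n_views = 3, time_per_view = 5)
    bank <- make_psf_bank(spec, orbit, b$activity)
    set.seed(11)
    y <- array(runif(bank$nu * bank$nv * 3), c(bank$nu, bank$nv, 3))
    Ax <- forward_project(b$activity, b$density, spec, orbit, bank)
    Aty <- back_project(y, b$activity, b$density, spec, orbit, bank)
    lhs <- sum(Ax * y)
    rhs <- sum(b$activity$data * Aty)
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-5)
  }
})

test_that("the EM update has the MLEM fixed point and stays non-negative", {
  b <- small_bundle()
  spec <- make_collimator("conebeam", 50)
  orbit <- plan_orbit(b, spec, n_views = 4, time_per_view = 10)
  # measured == forward(x0): one full-MLEM iteration must not move x0
  ps <- project(b, spec, orbit, n_scatter_histories = 0)
  st <- recon_settings(n_subsets = 1, n_iterations = 1,
                       scatter_mode = "none")
  rec <- osem(ps, spec, orbit, b$density, st,
              init = b$activity)
  mask <- rec$mask & b$activity$data > 0
  rel <- abs(rec$estimate$data[mask] - b$activity$data[mask]) /
    b$activity$data[mask]
  expect_lt(max(rel), 1e-6)
  # non-negativity after several noisy OSEM iterations
  cnt <- add_poisson(ps, seed = 3)
  st2 <- recon_settings(n_subsets = 4, n_iterations = 3,
                        scatter_mode = "none")
  rec2 <- osem(cnt, spec, orbit, b$density, st2)
  expect_true(all(rec2$estimate$data >= 0))
})

test_that("noiseless reconstruction recovers the phantom activity", {
  b <- small_bundle()
  spec <- make_collimator("conebeam", 50)
  orbit <- plan_orbit(b, spec, n_views = 8, time_per_view = 20)
  ps <- project(b, spec, orbit, n_scatter_histories = 0)
  st <- recon_settings(scatter_mode = "none", n_subsets = 4,
                       n_iterations = 10)
  rec <- osem(ps, spec, orbit, b$density, st)
  voi <- b$activity$data > 0
  recov <- 100 * sum(rec$estimate$data[voi]) / sum(b$activity$data[voi])
  expect_gt(recov, 95)
  expect_lt(recov, 105)
  # total activity conserved within a few percent
  expect_equal(sum(rec$estimate$data), sum(b$activity$data),
               tolerance = 0.05)
  # initialization invariance of the converged recovery
  init2 <- voxel_volume(array(7, dim(b$activity$data)),
                        b$activity$voxel_mm, b$activity$origin,
                        "activity_Bq")
  rec2 <- osem(ps, spec, orbit, b$density, st, init = init2)
  recov2 <- 100 * sum(rec2$estimate$data[voi]) / sum(b$activity$data[voi])
  expect_lt(abs(recov - recov2), 0.5)
})

test_that("dual-energy-window scatter term is linear in k and smooths the window", {
  b <- small_bundle()
  spec <- make_collimator("conebeam", 50)
  orbit <- plan_orbit(b, spec, n_views = 2, time_per_view = 10)
  set.seed(8)
  ps <- project(b, spec, orbit, n_scatter_histories = 5000)
  cnt <- add_poisson(ps, seed = 4)
  s1 <- scatter_estimate_dew(cnt, k = 0.5)
  s2 <- scatter_estimate_dew(cnt, k = 1.0)
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
  expect_equal(sum(scatter_estimate_dew(cnt, k = 0)), 0)
  # totals preserved by the interior smoothing (counts live mid-detector)
  expect_equal(sum(s1), 0.5 * sum(cnt$windows$scatter), tolerance = 0.02)
  # k = 0 reconstruction is identical to no scatter correction
  stn <- recon_settings(scatter_mode = "none", n_iterations = 2,
                        n_subsets = 2)
  std <- recon_settings(scatter_mode = "dew", dew_k = 0, n_iterations = 2,
                        n_subsets = 2)
  rn <- osem(cnt, spec, orbit, b$density, stn)
  rd <- osem(cnt, spec, orbit, b$density, std)
  expect_equal(rn$estimate$data, rd$estimate$data, tolerance = 1e-9)
})

test_that("MC scatter estimate tracks the density map", {
  b <- small_bundle()
  spec <- make_collimator("conebeam", 50)
  orbit <- plan_orbit(b, spec, n_views = 2, time_per_view = 10)
  st <- recon_settings(scatter_mode = "mc", mc_histories = 3000)
  zero_dens <- voxel_volume(array(0, dim(b$density$data)),
                            b$density$voxel_mm, b$density$origin,
                            "density")
  set.seed(2)
  s0 <- scatter_estimate_mc(b$activity, zero_dens, spec, orbit, st)
  expect_equal(sum(s0), 0)
  set.seed(2)
  s1 <- scatter_estimate_mc(b$activity, b$density, spec, orbit, st)
  expect_gt(sum(s1), 0)
})

test_that("optimal k search finds a constructed optimum and orders MSE", {
  ph <- small_liver()
  spec <- make_collimator("conebeam", 50)
  orbit <- plan_orbit(ph, spec, n_views = 8, time_per_view = 20)
  set.seed(12)
  ps <- project(ph, spec, orbit, n_scatter_histories = 5e4, seed = 12)
  cnt <- add_poisson(ps, seed = 13)
  st <- recon_settings(scatter_mode = "dew", n_iterations = 5,
                       n_subsets = 4)
  ks <- optimal_k_search(cnt, ph, spec, orbit, st,
                         k_grid = c(0.2, 0.35, 0.5, 0.65, 0.8, 0.95, 1.1),
                         refine = FALSE)
  tab <- ks$table
  expect_true(ks$k_opt > 0.2 && ks$k_opt < 1.1)
  # the k* reconstruction can't be worse than clinical k = 0.5
  mse_at <- function(k) {
    s <- st; s$dew_k <- k
    rec <- osem(cnt, spec, orbit, ph$density, s)
    liver <- ph$labels$data == 2L
    mean((rec$estimate$data[liver] - ph$activity$data[liver])^2)
  }
  expect_lte(min(tab$mse), mse_at(0.5) * (1 + 1e-9))
  # local convexity around the minimum on the evaluated grid
  i <- which.min(tab$mse)
  expect_true(tab$mse[i - 1] > tab$mse[i] && tab$mse[i + 1] > tab$mse[i])
})

test_that("crystal enlargement removes clipping but keeps the model", {
  ph <- small_liver()
  spec <- make_collimator("conebeam", 50)
  orbit <- plan_orbit(ph, spec, n_views = 4, time_per_view = 20)
  spec_inf <- expand_crystal(spec, 2.5)
  expect_equal(spec_inf$crystal_mm, spec$crystal_mm * 2.5)
  ps_f <- project(ph, spec, orbit, n_scatter_histories = 0)
  ps_i <- project(ph, spec_inf, orbit, n_scatter_histories = 0)
  # nothing is lost on the enlarged crystal
  expect_gte(sum(ps_i$windows$photopeak), sum(ps_f$windows$photopeak))
  # parallel collimator with the phantom under the crystal: no change
  par <- make_collimator("parallel")
  b <- small_bundle()
  orb <- plan_orbit(b, par, n_views = 4, time_per_view = 10)
  p1 <- project(b, par, orb, n_scatter_histories = 0)
  p2 <- project(b, expand_crystal(par, 2), orb, n_scatter_histories = 0)
  expect_equal(sum(p1$windows$photopeak), sum(p2$windows$photopeak),
               tolerance = 1e-6)
})
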