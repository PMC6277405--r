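test_that("Compton kinematics match the closed-form energy shift", {
  expect_equal(compton_scatter_energy(140, 0), 140)
  # E' = E / (1 + (E/mc2)(1 - cos)); frozen from the closed form
  expect_equal(compton_scatter_energy(140, pi), 90.443, tolerance = 1e-3)
  expect_equal(compton_scatter_energy(140, pi / 2), 109.893, tolerance = 1e-3)
  th <- seq(0, pi, length.out = 40)
  expect_true(all(diff(compton_scatter_energy(140, th)) < 0))
})

test_that("Klein-Nishina sampling reproduces the analytic distribution", {
  # numeric-integration oracle for bin probabilities at 140 keV
  alpha <- 140 / 510.999
  f <- function(c) {
    r <- 1 / (1 + alpha * (1 - c))
    r^2 * (1 / r + r - (1 - c^2))
  }
  norm <- integrate(f, -1, 1)$value
  breaks <- seq(-1, 1, length.out = 21)
  p <- vapply(seq_len(20), function(i)
    integrate(f, breaks[i], breaks[i + 1])$value / norm, 0)
  set.seed(31)
  n <- 1e6
  s <- sample_compton(140, n)
  h <- tabulate(findInterval(s[, "cos_theta"], breaks,
                             rightmost.closed = TRUE), 20)
  # 3-sigma multinomial bands per bin
  z <- (h - n * p) / sqrt(n * p * (1 - p))
  expect_true(all(abs(z) < 3.5))
  expect_lt(mean(abs(z) > 3), 0.06)
  # scattered energies consistent with the kinematic formula
  expect_equal(s[1:50, "energy_keV"],
               compton_scatter_energy(140, acos(s[1:50, "cos_theta"])),
               tolerance = 1e-7)
  # analytic mean scattered energy vs sample mean
  me <- integrate(function(c) f(c) * 140 / (1 + alpha * (1 - c)),
                  -1, 1)$value / norm
  expect_equal(mean(s[, "energy_keV"]), me, tolerance = 2e-3)
})

test_that("Klein-Nishina sampling approaches the Thomson shape at low energy", {
  set.seed(5)
  s <- sample_compton(0.5, 2e5)
  # Thomson: p(c) proportional to 1 + c^2 -> E[c^2] = 2/5... compute:
  # int c^2 (1+c^2) / int (1+c^2) = (2/3·... ) use numeric oracle
  num <- integrate(function(c) c^2 * (1 + c^2), -1, 1)$value /
    integrate(function(c) 1 + c^2, -1, 1)$value
  expect_equal(mean(s[, "cos_theta"]^2), num, tolerance = 0.01)
  expect_equal(mean(s[, "cos_theta"]), 0, tolerance = 0.01)
})

test_that("sampling is reproducible from the seed", {
  set.seed(99); a <- sample_compton(140, 1000)
  set.seed(99); b <- sample_compton(140, 1000)
  expect_identical(a, b)
})

test_that("energy windows have the stated default bounds", {
  pp <- photopeak_window()
  expect_equal(c(pp$lo, pp$hi), c(129.5, 150.5))
  sw <- scatter_window()
  expect_equal(c(sw$lo, sw$hi), c(99, 121))
})

test_that("window detection probability matches the Gaussian tail integral", {
  pp <- photopeak_window()
  expect_equal(window_detection_prob(140, pp, 0), 1)
  expect_equal(window_detection_prob(90, pp, 0), 0)
  # error-function closed form at 125 keV with 9.9% FWHM at 140
  s125 <- 0.099 * 140 * sqrt(125 / 140) / (2 * sqrt(2 * log(2)))
  want <- pnorm(150.5, 125, s125) - pnorm(129.5, 125, s125)
  expect_equal(window_detection_prob(125, pp, 0.099), want,
               tolerance = 1e-6)
  # monotone in window width
  w <- seq(0.05, 0.4, by = 0.05)
  p <- vapply(w, function(ww)
    window_detection_prob(132, energy_window(140, ww), 0.099), 0)
  expect_true(all(diff(p) > 0))
})

test_that("attenuation table has physical structure", {
  tab <- material_table()
  for (m in unique(tab$material)) {
    sub <- tab[tab$material == m, ]
    sub <- sub[order(sub$energy_keV), ]
    expect_true(all(diff(sub$mu_total_cm1) < 0))
    expect_true(all(sub$mu_compton_cm1 <= sub$mu_total_cm1))
  }
})

test_that("line attenuation matches closed forms and is symmetric", {
  vox <- 5
  n <- 41
  dens <- array(0, c(n, n, n))
  vac <- voxel_volume(dens, vox, semantics = "density")
  p0 <- c(-80, 3, 7); p1 <- c(80, 3, 7)
  expect_equal(line_attenuation(vac, p0, p1), 1, tolerance = 1e-9)
  dens[] <- 0.0012  # air: nearly transparent over 16 cm
  air <- voxel_volume(dens, vox, semantics = "density")
  expect_gt(line_attenuation(air, p0, p1), 0.995)

  dens[] <- 1
  water <- voxel_volume(dens, vox, semantics = "density")
  # 10 cm of water at 140 keV, closed form from the packaged table
  mu <- mu_of("water", 140)
  expect_equal(line_attenuation(water, c(-50, 0, 0), c(50, 0, 0)),
               exp(-10 * mu), tolerance = 1e-9)
  # direction reversal
  a <- line_attenuation(water, c(-41, -13, 22), c(37, 29, -18))
  b <- line_attenuation(water, c(37, 29, -18), c(-41, -13, 22))
  expect_equal(a, b, tolerance = 1e-12)
  # multiplicative over concatenated segments (midpoint on the ray)
  pm <- c(-41, -13, 22) + 0.4 * (c(37, 29, -18) - c(-41, -13, 22))
  ab <- line_attenuation(water, c(-41, -13, 22), pm) *
    line_attenuation(water, pm, c(37, 29, -18))
  expect_equal(a, ab, tolerance = 1e-9)
  # oblique ray closed form
  p0 <- c(-30, -40, 0); p1 <- c(30, 40, 0)
  expect_equal(line_attenuation(water, p0, p1),
               exp(-10 * mu), tolerance = 1e-9)
  # transmission in (0, 1]
  expect_true(a > 0 && a <= 1)
  # degenerate ray
  expect_equal(line_attenuation(water, pm, pm), 1)
})
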