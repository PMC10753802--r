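# Estimator tests on closed-form 1D benchmarks.  The double well
# U = h ((x/w)^2 - 1)^2 has an exactly known profile (the PMF along x of
# a 1D system is the potential itself), so every estimator can be
# checked against the analytic curve.

kB <- 0.008314463

test_that("WTM-inversion identities: flat bias, MtD limit", {
  g <- bias_grid(-2, 2, 0.05, 50)
  g$ubias[] <- 7.5
  prof <- pmf_from_wtm(g, temperature = 300, delta_T = 5000)
  expect_true(all(prof$energy == 0))
  # deltaT -> Inf gives the plain inversion factor -1
  g$ubias <- seq(0, 5, length.out = g$n)
  p_inf <- pmf_from_wtm(g, 300, Inf)
  expect_equal(max(p_inf$energy), 5, tolerance = 1e-12)
  p_wtm <- pmf_from_wtm(g, 300, 3000)
  expect_equal(max(p_wtm$energy), 5*(300 + 3000)/3000, tolerance = 1e-12)
  expect_error(pmf_from_wtm(bias_grid(-2, 2, 0.05), 300), "empty")
})

test_that("force integration: constant and zero mean force", {
  g <- bias_grid(0, 1, 0.01, 50)
  g$count[] <- 100
  prof <- pmf_from_forces(g)
  expect_true(all(abs(prof$energy) < 1e-12))   # zero force -> flat
  g$fsum <- rep(300, g$n)*g$count               # mean force 300 over width 1
  prof <- pmf_from_forces(g)
  expect_equal(max(prof$energy), 300*(g$n - 1)*g$bin, tolerance = 1e-9)
  # a gap splits the profile
  g$count[40:45] <- 0
  prof <- pmf_from_forces(g, min_count = 1)
  expect_true(all(is.na(prof$energy[40:45])))
  expect_true(all(is.finite(prof$energy[1:39])))
})

test_that("window assignment conserves counts and breaks ties downward", {
  centers <- c(0, 0.1, 0.2, 0.3)
  lam <- c(0, 0.1, 0.3, 0.099, 0.05, -5, 5)
  aw <- assign_windows(lam, centers)
  expect_equal(sum(aw$counts), length(lam))
  expect_equal(aw$index[1:3], c(1, 2, 4))   # exact centres map identically
  expect_equal(aw$index[6], 1)              # clamped at the edges
  expect_equal(aw$index[7], 4)
  # midpoint goes to the lower-index window
  expect_equal(assign_windows(0.05, centers)$index, 1)
  expect_equal(assign_windows(0.15, centers)$index, 2)
})

test_that("histogram PMF of Boltzmann samples recovers a harmonic profile", {
  set.seed(21)
  kk <- 60; Tk <- 300
  x <- rnorm(2e5, 0, sqrt(kB*Tk/kk))
  prof <- pmf_from_histogram(x, Tk, breaks = seq(-0.6, 0.6, 0.02),
                             blocks = 10)
  sel <- abs(prof$center) < 0.35
  fit <- lm(prof$energy[sel] ~ I(prof$center[sel]^2))
  expect_equal(unname(coef(fit)[2]), kk/2, tolerance = 0.05)
  # confidence bands exist and are positive where defined
  expect_true(any(is.finite(prof$ci95)))
  expect_true(all(prof$ci95[is.finite(prof$ci95)] >= 0))
})

test_that("confidence half-widths shrink like 1/sqrt(n)", {
  set.seed(8)
  Tk <- 300
  mk <- function(n) {
    x <- rnorm(n, 0, 0.2)
    p <- pmf_from_histogram(x, Tk, seq(-0.5, 0.5, 0.05), blocks = 10)
    mean(p$ci95[abs(p$center) < 0.3], na.rm = TRUE)
  }
  c1 <- mk(4e3); c2 <- mk(6.4e4)   # 16x the data -> ~4x smaller ci
  expect_equal(c1/c2, 4, tolerance = 0.5)
})

test_that("barrier extraction from synthetic profiles", {
  x <- seq(-1.5, 1.5, 0.01)
  # symmetric double well of depth 5
  prof <- fep(x, 5*(x^2 - 1)^2, coord = "x")
  b <- barrier_from_pmf(prof, c(-1.2, -0.8), c(0.8, 1.2))
  expect_equal(b$barrier, 5, tolerance = 1e-9)
  expect_equal(b$delta_A, 0, tolerance = 1e-9)
  # monotonically increasing profile: barrier equals total rise
  prof2 <- fep(x, 2*(x + 1.5), coord = "x")
  b2 <- barrier_from_pmf(prof2, c(-1.5, -1.4), c(1.4, 1.5))
  expect_equal(b2$barrier, b2$delta_A, tolerance = 1e-9)
  expect_equal(b2$delta_A, 2*(x[length(x)] - x[1]), tolerance = 0.05)
  # undefined bins in a required range raise an error
  e <- 5*(x^2 - 1)^2; e[x > 0.9 & x < 1.1] <- NA
  expect_error(barrier_from_pmf(fep(x, e), c(-1.2, -0.8), c(0.8, 1.2)),
               "undefined")
})

test_that("eABF on a harmonic well recovers the curvature within 5%", {
  kk <- 100
  pot <- harmonic_well(kk)
  cfg <- sampler_config(bias = "eabf", temperature = 300, friction = 0.02,
                        mass = 10, ext_mass = 20, ext_sigma = 0.02,
                        ext_friction = 0.02, stabilize = FALSE,
                        steps = 6e5, stride = 10, dt = 0.5,
                        grid_min = -0.8, grid_max = 0.8, grid_bin = 0.02,
                        abf_nfull = 50, conf_k = 0,
                        path_update_interval = 0, pmf_interval = 0,
                        fp_threshold = Inf)
  sim <- run_simulation(pot, cfg, x0 = 0, seed = 5)
  prof <- pmf_from_forces(sim$grid, min_count = 200)
  sel <- is.finite(prof$energy) & abs(prof$center) < 0.4
  fit <- lm(prof$energy[sel] ~ I(prof$center[sel]^2))
  expect_equal(unname(coef(fit)[2]), kk/2, tolerance = 0.05)
})

test_that("all three estimators agree on a converged 1D double well", {
  # benchmark conditions: barrier 10 kJ/mol at 300 K, WTM-eABF sampling
  h <- 10
  pot <- double_well(h, 1)
  cfg <- sampler_config(bias = "wtm-eabf", temperature = 300,
                        friction = 0.02, mass = 10, ext_mass = 20,
                        ext_sigma = 0.02, ext_friction = 0.02,
                        stabilize = FALSE, hill_height = 0.2,
                        hill_sigma = 0.05, hill_interval = 25,
                        delta_T = 3000, steps = 2e6, stride = 10,
                        dt = 0.5, grid_min = -1.7, grid_max = 1.7,
                        grid_bin = 0.02, abf_nfull = 50, conf_k = 0,
                        path_update_interval = 0, pmf_interval = 0,
                        fp_threshold = Inf)
  sim <- run_simulation(pot, cfg, x0 = -1, seed = 17)
  exact <- function(x) h*(x^2 - 1)^2

  p_force <- pmf_from_forces(sim$grid, min_count = 100)
  rng <- c(-1.25, 1.25)
  expect_lt(fep_rmse(p_force, exact, rng), 1)

  # MBAR reweighting of the lambda-windowed trajectory
  p_mbar <- suppressWarnings(mbar_pmf(sim, breaks = seq(-1.7, 1.7, 0.05), sub = 4))
  expect_lt(fep_rmse(p_mbar, exact, rng, max_undefined = 2), 1)

  # WTM inversion alone cannot know the ABF share of the bias; compare
  # the composite estimate (inversion + integrated ABF mean force is the
  # force-integration estimator above) on shape: cross-estimator RMSE
  expect_lt(fep_rmse(p_force, p_mbar, rng, max_undefined = 2), 1)

  # barrier from the force profile within 10% of the analytic value
  b <- barrier_from_pmf(p_force, c(-1.2, -0.8), c(0.8, 1.2))
  expect_equal(b$barrier, h, tolerance = 0.1)
})

test_that("WTM alone on the double well recovers the barrier within 10%", {
  h <- 10
  pot <- double_well(h, 1)
  cfg <- sampler_config(bias = "wtm", temperature = 300, friction = 0.02,
                        mass = 10, hill_height = 0.2, hill_sigma = 0.05,
                        hill_interval = 25, delta_T = 3000,
                        steps = 2e6, stride = 10, dt = 0.5,
                        grid_min = -1.7, grid_max = 1.7, grid_bin = 0.02,
                        conf_k = 0, path_update_interval = 0,
                        pmf_interval = 0, fp_threshold = Inf)
  sim <- run_simulation(pot, cfg, x0 = -1, seed = 23)
  prof <- pmf_from_wtm(sim$grid, 300, 3000)
  b <- barrier_from_pmf(prof, c(-1.2, -0.8), c(0.8, 1.2))
  expect_equal(b$barrier, h, tolerance = 0.1)
  expect_lt(fep_rmse(prof, function(x) h*(x^2 - 1)^2, c(-1.25, 1.25)), 1.5)
})
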