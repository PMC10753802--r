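test_that("zero-friction integration conserves energy (symplectic limit)", {
  pot <- muller_brown()
  m <- mb_minima(pot)
  cfg <- short_config(bias = "none", friction = 0, temperature = 50,
                      steps = 1e4, stride = 1, dt = 0.5,
                      fp_threshold = Inf)
  sim <- run_simulation(pot, cfg, x0 = m$deep + c(0.01, 0.01), seed = 1)
  tr <- sim$trajectory
  # total energy = potential + kinetic (from recorded temperature)
  ke <- tr$temp*2*0.008314463/2
  etot <- tr$epot + ke
  expect_lt(diff(range(etot)), 1e-3)
})

test_that("identical seeds give bit-identical trajectories", {
  pot <- muller_brown()
  m <- mb_minima(pot)
  cfg <- short_config(bias = "wtm-eabf", steps = 5000, stride = 10)
  path <- guess_path(pot, 10, ends = rbind(m$shallow, m$deep))
  s1 <- run_simulation(pot, cfg, path = path, x0 = m$shallow, seed = 99)
  s2 <- run_simulation(pot, cfg, path = path, x0 = m$shallow, seed = 99)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(unclass(s1$path_final), unclass(s2$path_final))
  s3 <- run_simulation(pot, cfg, path = path, x0 = m$shallow, seed = 100)
  expect_false(identical(s3$trajectory$x, s1$trajectory$x))
})

test_that("thermostatted harmonic well equilibrates to the target temperature", {
  # equipartition oracle: long Langevin run at 300 K in a harmonic well
  pot <- harmonic_well(c(80, 80))
  cfg <- sampler_config(bias = "none", temperature = 300, friction = 0.01,
                        mass = 200, steps = 4e5, stride = 10, dt = 0.5,
                        pmf_interval = 0, path_update_interval = 0,
                        fp_threshold = Inf)
  sim <- run_simulation(pot, cfg, x0 = c(0, 0), seed = 7)
  tr <- sim$trajectory
  burn <- tr$time_fs > 20000
  expect_equal(mean(tr$temp[burn]), 300, tolerance = 2/300*3)
  # Boltzmann position variance: var(x) = kBT/k within 3 SE
  v <- var(tr$x[burn])
  vth <- 0.008314463*300/80
  nefff <- sum(burn)/50  # crude decorrelation allowance
  se <- vth*sqrt(2/nefff)
  expect_lt(abs(v - vth), 3*se)
})

test_that("rolling temperature averages the kinetic temperature", {
  pot <- harmonic_well(c(80, 80))
  cfg <- short_config(bias = "none", temperature = 300, friction = 0.01,
                      steps = 1e5, fp_threshold = Inf)
  sim <- run_simulation(pot, cfg, seed = 3)
  rt <- rolling_temperature(sim, window_fs = 1000)
  # window of 1 ps at dt 0.5 and stride 10 -> 200 frames
  expect_equal(sum(is.na(rt)), 199)
  expect_equal(mean(rt, na.rm = TRUE), 300, tolerance = 0.05)
  # constant input gives constant output
  sim2 <- sim; sim2$trajectory$temp <- 42
  expect_equal(unique(na.omit(rolling_temperature(sim2))), 42)
  expect_error(rolling_temperature(sim, window_fs = 1), "window")
})

test_that("coupling forces follow k = kB T / sigma^2 and Newton's third law", {
  cf <- coupling_forces(s = 0.5, grad_s = c(0.3, -0.4), lambda = 0.48,
                        sigma = 0.01, temperature = 50)
  expect_equal(cf$k, 0.008314463*50/1e-4, tolerance = 1e-12)
  expect_equal(cf$k, 4157.2315, tolerance = 1e-4)
  # lambda = s: no force, no energy
  cf0 <- coupling_forces(0.5, c(0.3, -0.4), 0.5, 0.01, 50)
  expect_equal(cf0$f_lambda, 0)
  expect_equal(cf0$energy, 0)
  expect_equal(cf0$f_coords, c(0, 0))
  # action equals reaction through the CV gradient: the generalized
  # force on s is minus the force on lambda
  gen_force_on_s <- sum(cf$f_coords*c(0.3, -0.4))/sum(c(0.3, -0.4)^2)
  expect_equal(gen_force_on_s, -cf$f_lambda, tolerance = 1e-10)
})

test_that("hill deposition follows the well-tempered height schedule", {
  g <- bias_grid(-0.1, 1.1, 0.01, 50)
  # first hill at a fresh grid: height exactly h0
  g <- deposit_hill(g, 0.505, height = 0.01, sigma = 0.05, delta_T = 5000)
  expect_equal(max(g$ubias), 0.01, tolerance = 1e-6)
  # bias at kB deltaT ln 2 halves the next hill
  g2 <- bias_grid(-0.1, 1.1, 0.01, 50)
  g2$ubias[] <- 0.008314463*5000*log(2)
  g3 <- deposit_hill(g2, 0.505, 0.01, 0.05, 5000)
  expect_equal(max(g3$ubias - g2$ubias), 0.005, tolerance = 1e-6)
  # successive hill heights at a fixed centre are non-increasing, and
  # the bias is non-decreasing everywhere
  g <- bias_grid(-0.1, 1.1, 0.01, 50)
  prev_h <- Inf; prev_u <- g$ubias
  for (i in 1:20) {
    g <- deposit_hill(g, 0.3, 0.01, 0.05, 5000)
    dh <- max(g$ubias - prev_u)
    expect_lte(dh, prev_h + 1e-12)
    expect_true(all(g$ubias >= prev_u - 1e-15))
    prev_h <- dh; prev_u <- g$ubias
  }
  # plain MtD (infinite delta T): heights constant
  g <- bias_grid(-0.1, 1.1, 0.01, 50)
  g <- deposit_hill(g, 0.505, 0.01, 0.05, Inf)
  g4 <- deposit_hill(g, 0.505, 0.01, 0.05, Inf)
  expect_equal(max(g4$ubias - g$ubias), 0.01, tolerance = 1e-9)
  # outside the grid: skipped with a warning
  expect_warning(deposit_hill(g, 5, 0.01, 0.05), "skipped")
})

test_that("ABF force ramps linearly with the bin count", {
  g <- bias_grid(-0.1, 1.1, 0.01, nfull = 50)
  expect_equal(abf_force(g, 0.5), 0)          # empty bin
  j <- floor((0.5 - g$min)/g$bin) + 1
  g$count[j] <- 25; g$fsum[j] <- 25*12        # mean force 12
  expect_equal(abf_force(g, 0.5), 0.5*12)     # half ramp
  g$count[j] <- 50; g$fsum[j] <- 50*12
  expect_equal(abf_force(g, 0.5), 12)         # full ramp
  g$count[j] <- 500; g$fsum[j] <- 500*12
  expect_equal(abf_force(g, 0.5), 12)         # capped at the mean
  # ramp never exceeds the bin mean force
  for (n in c(1, 10, 49, 50, 200)) {
    g$count[j] <- n; g$fsum[j] <- n*(-7)
    expect_lte(abs(abf_force(g, 0.5)), 7 + 1e-12)
  }
})

test_that("stabilization translates lambda only across CV jumps", {
  # jump scenario: CV steps by 0.3 while the spring extension was 0.005
  expect_equal(stabilize_lambda(lambda_prev = 0.405, s_prev = 0.40,
                                s_curr = 0.70, sigma = 0.01),
               0.705, tolerance = 1e-12)
  # coupling energy is continuous: extension identical before and after
  ext_before <- 0.40 - 0.405
  ext_after <- 0.70 - 0.705
  expect_equal(ext_before, ext_after)
  # ordinary dynamics (sub-sigma change): untouched
  expect_equal(stabilize_lambda(0.405, 0.400, 0.403, 0.01), 0.405)
  # contract: after any correction the extension never exceeds
  # max(sigma, previous extension) beyond the sub-threshold drift
  set.seed(5)
  for (i in 1:200) {
    lp <- runif(1); sp <- lp + runif(1, -0.03, 0.03)
    sc <- sp + runif(1, -0.5, 0.5)
    lc <- stabilize_lambda(lp, sp, sc, 0.01)
    expect_lte(abs(sc - lc),
               max(0.01, abs(sp - lp)) + 0.01 + 1e-12)
  }
})

test_that("confinement force is one-sided, continuous, and harmonic", {
  gd <- c(0.6, 0.8)
  expect_equal(confinement_force(0.05, gd, 0.1, 500)$force, c(0, 0))
  expect_equal(confinement_force(0.1, gd, 0.1, 500)$force, c(0, 0))
  cf <- confinement_force(0.1 + 0.02, gd, 0.1, 500)
  expect_equal(cf$force, -500*0.02*gd, tolerance = 1e-12)
  expect_equal(cf$energy, 0.5*500*0.02^2, tolerance = 1e-12)
})

test_that("frame bookkeeping: count, time, and energy sanity", {
  pot <- double_well(10, 1)
  cfg <- short_config(bias = "none", temperature = 300, friction = 0.01,
                      mass = 50, steps = 12345, stride = 10,
                      grid_min = -2, grid_max = 2, grid_bin = 0.05,
                      fp_threshold = Inf)
  sim <- run_simulation(pot, cfg, x0 = 1, seed = 2)
  tr <- sim$trajectory
  expect_equal(nrow(tr), 12345 %/% 10)
  expect_equal(tr$time_fs, tr$step*cfg$dt)
})

test_that("unbiased 1D harmonic sampling reproduces the Boltzmann variance", {
  pot <- harmonic_well(120)
  cfg <- sampler_config(bias = "none", temperature = 300, friction = 0.02,
                        mass = 100, steps = 6e5, stride = 10, dt = 0.5,
                        pmf_interval = 0, path_update_interval = 0,
                        fp_threshold = Inf)
  sim <- run_simulation(pot, cfg, x0 = 0, seed = 13)
  x <- sim$trajectory$x[sim$trajectory$time_fs > 10000]
  vth <- 0.008314463*300/120
  neff <- length(x)/40
  se <- vth*sqrt(2/neff)
  expect_lt(abs(var(x) - vth), 3*se)
})
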