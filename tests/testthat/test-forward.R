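test_that("forward simulation is linear and matches the direct oracle", {
  p <- tiny_params()
  sch <- build_schedule(trajectory_config("ASOS", 3, p))
  maps1 <- coil_sensitivities(1, c(3, 32, 32), smoothness = Inf)
  vol <- array(0, c(3, 32, 32)); vol[2, 10:20, 8:25] <- 1
  scn <- starstack:::.phantom_scene(array(as.complex(vol), c(1, 3, 32, 32)),
                                    0, c(2, 2, 6), list())
  kd <- simulate_kspace(scn, sch, maps1)
  co <- spoke_coordinates(sch, p)
  # DC sample equals the sum of intensities
  i0 <- which(abs(co[, , 1]) < 1e-9 & abs(co[, , 2]) < 1e-9 &
                abs(co[, , 3]) < 1e-9, arr.ind = TRUE)
  expect_equal(kd$samples[i0[1, 1], i0[1, 2], 1], sum(vol) + 0i,
               tolerance = 1e-6)
  # full oracle comparison
  oracle <- direct_sos_forward(array(as.complex(vol), c(3, 32, 32)), co, 32)
  expect_lt(rel_err(kd$samples[, , 1], oracle), 1e-6)
  # linearity
  scn3 <- scn; scn3$frames <- 3 * scn$frames
  kd3 <- simulate_kspace(scn3, sch, maps1)
  expect_equal(kd3$samples, 3 * kd$samples, tolerance = 1e-12)
  # zero scene -> exactly zero without noise
  scn0 <- scn; scn0$frames[] <- 0i
  kd0 <- simulate_kspace(scn0, sch, maps1, noise_sd = 0)
  expect_true(all(kd0$samples == 0))
})

test_that("perturbations off gives bitwise-identical clean data", {
  p <- tiny_params()
  sch <- build_schedule(trajectory_config("RSOS_PSI1", 3, p))
  sc <- tiny_scene()
  maps <- tiny_maps()
  a <- simulate_kspace(sc, sch, maps, seed = 5)
  b <- simulate_kspace(sc, sch, maps, gradient_delay_samples = 0,
                       eddy_coupling = 0, seed = 5)
  expect_identical(a$samples, b$samples)
})

test_that("noise realisations are reproducible and follow the coil covariance", {
  p <- sequence_params(matrix = 8, n_readout = 128, n_slices = 1,
                       oversampling_factor = 1)
  sch <- build_schedule(trajectory_config("RADIAL2D", 800, p))
  maps <- coil_sensitivities(4, c(1, 8, 8), seed = 5)
  scn0 <- starstack:::.phantom_scene(array(0i, c(1, 1, 8, 8)), 0,
                                     c(2, 2, 6), list())
  kd <- simulate_kspace(scn0, sch, maps, noise_sd = 1, seed = 11)
  kd2 <- simulate_kspace(scn0, sch, maps, noise_sd = 1, seed = 11)
  expect_identical(kd$samples, kd2$samples)
  x <- matrix(kd$samples, ncol = 4)  # 102400 samples
  emp <- empirical_cov(x)
  err <- sqrt(sum(Mod(emp - maps$noise_covariance)^2)) /
    sqrt(sum(Mod(maps$noise_covariance)^2))
  expect_lt(err, 0.05)
})

test_that("eddy-model per-event errors scale with the azimuthal jump", {
  p <- sequence_params(matrix = 32, n_readout = 64, n_slices = 7)
  s1 <- build_schedule(trajectory_config("RSOS_PSI1", 6, p))
  s9 <- build_schedule(trajectory_config("RSOS_PSI9", 6, p))
  sc <- static_phantom(32, 9, 1)
  maps <- coil_sensitivities(2, c(9, 32, 32), seed = 1)
  k1 <- simulate_kspace(sc, s1, maps, eddy_coupling = 0.01)
  k9 <- simulate_kspace(sc, s9, maps, eddy_coupling = 0.01)
  r <- mean(abs(k1$meta$event_shifts[-1])) / mean(abs(k9$meta$event_shifts[-1]))
  expect_equal(r, 111.25 / 18.71, tolerance = 0.01)
  # ASOS only jumps at star boundaries
  sa <- build_schedule(trajectory_config("ASOS", 6, p))
  ka <- simulate_kspace(sc, sa, maps, eddy_coupling = 0.01)
  shifts <- ka$meta$event_shifts
  expect_true(all(shifts[sa$kz_index != 0] == 0))
})

test_that("fully sampled acquisition uses the radial Nyquist spoke count", {
  sc <- tiny_scene()
  p <- tiny_params()  # 64 readout samples
  kd <- acquire_fully_sampled(sc, "ASOS", p)
  expect_equal(nrow(kd$schedule) / 3, 101)  # round(pi * 32)
  p256 <- sequence_params()
  expect_equal(round(pi * p256$n_readout / 2), 402)
  expect_equal(round(402 * p256$tr, 1), 1.2)  # scan time per slice, seconds
  expect_error(acquire_fully_sampled(cached("dyn_scene", dynamic_swallow_phantom()),
                                     "ASOS", p))
})
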