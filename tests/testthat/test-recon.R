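test_that("prewhitening yields identity covariance and flags degeneracy", {
  p <- sequence_params(matrix = 8, n_readout = 128, n_slices = 1,
                       oversampling_factor = 1)
  sch <- build_schedule(trajectory_config("RADIAL2D", 800, p))
  maps <- coil_sensitivities(4, c(1, 8, 8), seed = 5)
  scn0 <- starstack:::.phantom_scene(array(0i, c(1, 1, 8, 8)), 0,
                                     c(2, 2, 6), list())
  kd <- simulate_kspace(scn0, sch, maps, noise_sd = 1, seed = 11)
  kw <- prewhiten(kd)
  x <- matrix(kw$samples, ncol = 4)
  emp <- empirical_cov(x)
  expect_lt(sqrt(sum(Mod(emp - diag(4))^2)) / sqrt(4), 0.05)
  # identity covariance leaves the data unchanged
  kdi <- kd; kdi$noise_covariance <- diag(4) + 0i
  kwi <- prewhiten(kdi)
  expect_equal(kwi$samples, kdi$samples, tolerance = 1e-12)
  # singular covariance is rejected with a diagnostic
  kds <- kd
  kds$noise_covariance <- diag(c(1, 1, 1, 0)) + 0i
  expect_error(prewhiten(kds), "singular|positive")
})

test_that("gradient-delay estimation recovers simulated shifts", {
  p <- sequence_params(matrix = 64, n_readout = 128, n_slices = 1,
                       oversampling_factor = 1)
  sc <- cached("gd_scene", static_phantom(64, 1, 1))
  maps <- cached("gd_maps", coil_sensitivities(3, c(1, 64, 64), seed = 3))
  sch <- build_schedule(trajectory_config("RADIAL2D", 200, p))
  for (delay in c(0.5, 0, -0.3)) {
    kd <- simulate_kspace(sc, sch, maps, gradient_delay_samples = delay)
    kc <- gradient_delay_correct(kd)
    expect_equal(kc$meta$estimated_delay_samples, delay, tolerance = 0.05)
    if (delay == 0) {
      expect_lt(rel_err(kc$samples, kd$samples), 1e-3)
    }
  }
  # schedule without opposed pairs: warn and skip
  sch1 <- build_schedule(trajectory_config("RADIAL2D", 2, p))
  kd1 <- simulate_kspace(sc, sch1, maps)
  expect_warning(kc1 <- gradient_delay_correct(kd1), "skipped")
  expect_identical(kc1$samples, kd1$samples)
})

test_that("sensitivity estimation recovers smooth maps", {
  fx <- acc64()
  est <- estimate_sensitivities(fx$kd, lowres_fraction = 0.15)
  body <- fx$sc$ground_truth$support
  dgrid <- c(fx$nkz, 64, 64)
  # compare against rSOS-normalised truth with a per-coil complex scale
  rsos <- sqrt(apply(Mod(fx$maps$maps)^2, 2:4, sum))
  num <- 0; den <- 0
  for (ch in seq_len(dim(fx$maps$maps)[1])) {
    tm <- (array(fx$maps$maps[ch, , , ], dgrid) / rsos)[body]
    em <- array(est$maps[ch, , , ], dgrid)[body]
    al <- sum(Conj(em) * tm) / sum(Mod(em)^2)
    num <- num + sum(Mod(al * em - tm)^2)
    den <- den + sum(Mod(tm)^2)
  }
  expect_lt(sqrt(num / den), 0.10)
  # single constant coil: estimated map has uniform magnitude over support
  sc <- tiny_scene()
  one <- coil_sensitivities(1, c(3, 32, 32), smoothness = Inf)
  kd1 <- acquire_fully_sampled(sc, "ASOS", tiny_params(), one)
  est1 <- estimate_sensitivities(kd1)
  m <- Mod(array(est1$maps[1, , , ], c(3, 32, 32)))[sc$ground_truth$support]
  expect_lt(sd(m) / mean(m), 0.01)
})

test_that("CG-SENSE reconstructs the noiseless phantom and handles zero data", {
  fx <- acc64()
  truth <- array(fx$sc$frames[1, , , ], c(fx$nkz, 64, 64))
  rec <- array(fx$ref$frames[1, , , ], c(fx$nkz, 64, 64))
  body <- fx$sc$ground_truth$support
  a <- sum(Conj(rec[body]) * truth[body]) / sum(Mod(rec[body])^2)
  expect_lt(sqrt(sum(Mod(a * rec[body] - truth[body])^2) /
                   sum(Mod(truth[body])^2)), 0.02)
  # zero data -> zero image (tiny instance)
  kd0 <- cached("tiny_full", acquire_fully_sampled(tiny_scene(), "ASOS",
                                                   tiny_params(), tiny_maps()))
  kd0$samples[] <- 0i
  ref0 <- reference_recon(kd0, tiny_maps())
  expect_true(all(ref0$frames == 0))
})

test_that("whitened SENSE is invariant under invertible coil recombination", {
  p <- tiny_params()
  sc <- tiny_scene()
  maps <- tiny_maps()
  kd <- cached("tiny_full", acquire_fully_sampled(sc, "ASOS", p, maps))
  set.seed(8)
  tmat <- matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3, 3) +
    3 * diag(3)
  kd2 <- kd
  flat <- matrix(kd$samples, ncol = 3)
  kd2$samples <- array(flat %*% t(tmat), dim = dim(kd$samples))
  kd2$noise_covariance <- tmat %*% kd$noise_covariance %*% Conj(t(tmat))
  maps2 <- maps
  mflat <- matrix(aperm(maps$maps, c(2, 3, 4, 1)), ncol = 3)
  maps2$maps <- aperm(array(mflat %*% t(tmat), dim = c(3, 32, 32, 3)),
                      c(4, 1, 2, 3))
  r1 <- reference_recon(prewhiten(kd), maps)
  r2 <- reference_recon(prewhiten(kd2), maps2)
  expect_lt(rel_err(Mod(r1$frames), Mod(r2$frames)), 1e-3)
})

test_that("flat-field correction removes smooth shading", {
  # textureless body times a smooth coil-intensity profile: flat-fielding
  # must restore a flat interior (CoV reduced by at least half). The kernel
  # is scaled to the test's small 128 mm field of view; the interior region
  # stays a kernel width away from the body edge, where the blurred
  # denominator is dominated by tissue rather than background roll-off.
  g <- starstack:::.mm_coords(5, 64, 64, c(2, 2, 6))
  rho <- sqrt((g$x / 54)^2 + (g$y / 56)^2)  # cylinder through the slab
  body <- rho <= 1
  vol <- array(0, c(5, 64, 64))
  vol[body] <- 1
  shade <- 1 + 0.8 * g$x / 128
  shaded <- vol * shade
  ff <- flat_field(shaded, kernel_width_mm = 16, voxel_size = c(2, 2, 6))
  expect_true(all(is.finite(ff)))
  interior <- rho <= 0.6
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(ff[interior]), 0.5 * cv(shaded[interior]))
  # constant image maps to ~1
  const <- flat_field(array(2, c(3, 16, 16)), 32, c(2, 2, 6))
  expect_equal(range(const), c(1, 1), tolerance = 2e-3)
  expect_error(flat_field(array(0, c(3, 8, 8))), "zero")
})
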