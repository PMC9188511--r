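test_that("the 1D temporal TV prox solves the exact proximal problem", {
  set.seed(7)
  for (rep in 1:12) {
    n <- sample(2:25, 1)
    lam <- runif(1, 0.01, 2)
    y <- rnorm(n, sd = sample(c(0.1, 1, 5), 1))
    got <- starstack:::.tv1d_prox_cols(matrix(y, ncol = 1), lam)[, 1]
    expect_equal(got, tv_prox_dual_oracle(y, lam, 20000), tolerance = 1e-5)
  }
})

test_that("LLR prox soft-thresholds patch singular values", {
  set.seed(3)
  frames <- array(complex(real = rnorm(4 * 2 * 8 * 8),
                          imaginary = rnorm(4 * 2 * 8 * 8)),
                  dim = c(4, 2, 8, 8))
  out <- starstack:::.llr_prox(frames, thresh = 0.5, patch = 8)
  # one patch per slice: compare against direct SVD shrinkage
  for (z in 1:2) {
    M <- matrix(aperm(array(frames[, z, , ], c(4, 8, 8)), c(2, 3, 1)), 64, 4)
    sv <- La.svd(M)
    Mt <- sv$u %*% (pmax(sv$d - 0.5, 0) * sv$vt)
    got <- matrix(aperm(array(out$frames[, z, , ], c(4, 8, 8)), c(2, 3, 1)), 64, 4)
    expect_equal(got, Mt, tolerance = 1e-10)
  }
  # zero threshold returns the input and the exact nuclear norm
  id <- starstack:::.llr_prox(frames, 0, 8)
  expect_equal(id$frames, frames, tolerance = 1e-12)
})

test_that("with regularisation off, CS matches CG-SENSE on a full single frame", {
  p <- tiny_params()
  sc <- tiny_scene()
  maps <- tiny_maps()
  kd <- cached("tiny_full", acquire_fully_sampled(sc, "ASOS", p, maps))
  emaps <- cached("tiny_emaps", estimate_sensitivities(kd))
  ref <- reference_recon(kd, emaps, tol = 1e-7, max_iter = 60)
  b <- bin_frames(kd$schedule, 101)
  cs0 <- suppressWarnings(
    cs_recon(kd, b, emaps, recon_config(lambda_llr = 0, lambda_tv_time = 0,
                                        iterations = 150, tolerance = 1e-9)))
  expect_lt(nrmse(Mod(ref$frames), Mod(cs0$frames)), 0.01)
})

test_that("CS objective is non-increasing and patch-shift-seed independent", {
  p <- tiny_params()
  sc <- tiny_scene()
  maps <- tiny_maps()
  sched <- build_schedule(trajectory_config("RSOS_PSI1", 18, p))
  kd <- simulate_kspace(sc, sched, maps)
  b <- bin_frames(sched, 6)
  cs1 <- suppressWarnings(cs_recon(kd, b, maps, recon_config(iterations = 15, seed = 1)))
  expect_true(all(diff(cs1$objective) <= 1e-9 * abs(cs1$objective[-length(cs1$objective)])))
  cs2 <- suppressWarnings(cs_recon(kd, b, maps, recon_config(iterations = 15, seed = 99)))
  o1 <- tail(cs1$objective, 1)
  o2 <- tail(cs2$objective, 1)
  expect_lt(abs(o1 - o2) / o1, 0.01)
  # determinism under identical config
  cs1b <- suppressWarnings(cs_recon(kd, b, maps, recon_config(iterations = 15, seed = 1)))
  expect_identical(cs1$frames, cs1b$frames)
})

test_that("sliding window doubles the frame rate by interleaving two runs", {
  p <- tiny_params()
  sc <- tiny_scene()
  maps <- tiny_maps()
  sched <- build_schedule(trajectory_config("RSOS_PSI1", 24, p))
  kd <- simulate_kspace(sc, sched, maps)
  b <- bin_frames(sched, 6)
  cfg <- recon_config(iterations = 6)
  sw <- suppressWarnings(sliding_window(kd, b, maps, cfg))
  expect_equal(dim(sw$frames)[1], 2 * b$n_frames - 1)
  expect_equal(sw$frame_rate, 2 * b$frame_rate)
  expect_true(all(diff(sw$frame_times) > 0))
  # no blending: odd output frames are exactly the base run's frames
  cs1 <- suppressWarnings(cs_recon(kd, b, maps, cfg))
  for (f in seq_len(b$n_frames)) {
    expect_identical(sw$frames[2 * f - 1, , , ], cs1$frames[f, , , ])
  }
  # RSOS_GR is incompatible with a sliding window
  schg <- build_schedule(trajectory_config("RSOS_GR", 24, p))
  kdg <- simulate_kspace(sc, schg, maps)
  expect_error(sliding_window(kdg, bin_frames(schg, 6), maps, cfg),
               "sliding")
})

test_that("the 7-slice protocol reports 12 fps after sliding-window doubling", {
  p <- sequence_params(n_slices = 7)
  sch <- build_schedule(trajectory_config("ASOS", 12, p))
  b <- bin_frames(sch, 6)
  expect_equal(floor(2 * b$frame_rate), 12)
})
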