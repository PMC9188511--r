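test_that("tiny golden angles match the analytic formula and decrease", {
  expect_equal(round(tiny_golden_angle(1), 2), 111.25)
  expect_equal(round(tiny_golden_angle(9), 2), 18.71)
  tau <- (1 + sqrt(5)) / 2
  expect_equal(tiny_golden_angle(2), 180 / (tau + 1), tolerance = 1e-12)
  angles <- vapply(1:12, tiny_golden_angle, numeric(1))
  expect_true(all(diff(angles) < 0))
  expect_error(tiny_golden_angle(0))
  expect_error(tiny_golden_angle(1.5))
  expect_error(tiny_golden_angle(-3))
})

test_that("sequence parameters enforce their invariants and kz rounding", {
  p <- sequence_params()
  expect_equal(n_kz(p), 9L)  # 7 slices x 1.28 oversampling
  expect_equal(n_kz(sequence_params(n_slices = 21)), 27L)
  expect_error(sequence_params(tr = 0))
  expect_error(sequence_params(n_readout = 1))
  expect_error(sequence_params(oversampling_factor = 0.5))
})

test_that("schedules satisfy the pattern definitions", {
  p <- sequence_params()
  asos <- build_schedule(trajectory_config("ASOS", 5, p))
  expect_equal(nrow(asos), 5 * 9)
  # all events of one star share the star's azimuth; star 0 at 0 degrees
  expect_true(all(asos$azimuth_deg[asos$star_index == 0] == 0))
  for (s in 0:4) {
    expect_equal(unique(asos$azimuth_deg[asos$star_index == s]),
                 (s * tiny_golden_angle(1)) %% 360)
  }
  psi1 <- build_schedule(trajectory_config("RSOS_PSI1", 5, p))
  expect_equal(psi1$azimuth_deg[3], (2 * tiny_golden_angle(1)) %% 360)
  expect_equal(round(psi1$azimuth_deg[3], 2), 222.49)
  # continuity: increment identical within and across stars
  d <- diff(psi1$azimuth_deg) %% 360
  expect_equal(d, rep(tiny_golden_angle(1), length(d)), tolerance = 1e-9)
  psi9 <- build_schedule(trajectory_config("RSOS_PSI9", 5, p))
  d9 <- diff(psi9$azimuth_deg) %% 360
  expect_equal(d9, rep(tiny_golden_angle(9), length(d9)), tolerance = 1e-9)
  expect_equal((9 * tiny_golden_angle(9)) %% 360, 168.4267, tolerance = 1e-3)
  # event accounting and kz coverage for every pattern
  for (pat in c("ASOS", "RSOS_GR", "RSOS_PSI1", "RSOS_PSI9")) {
    sch <- build_schedule(trajectory_config(pat, 4, p))
    expect_equal(nrow(sch), 4 * 9)
    expect_true(all(diff(sch$global_index) == 1))
    for (s in unique(sch$star_index)) {
      expect_equal(sort(sch$kz_index[sch$star_index == s]), 0:8)
    }
    expect_true(all(sch$time_s == sch$global_index * p$tr))
  }
})

test_that("RSOS_PSI1 equals the classical golden-angle sequence event-for-event", {
  p <- sequence_params(n_slices = 1, oversampling_factor = 1)
  r2d <- build_schedule(trajectory_config("RADIAL2D", 40, p))
  ps1 <- build_schedule(trajectory_config("RSOS_PSI1", 40, p))
  expect_equal(r2d$azimuth_deg, ps1$azimuth_deg)
  expect_equal(r2d$kz_index, ps1$kz_index)
})

test_that("golden-angle azimuths are near-uniform for Fibonacci spoke counts", {
  phi <- (1 + sqrt(5)) / 2
  p <- sequence_params(n_slices = 1, oversampling_factor = 1)
  for (n in c(13, 21, 34)) {
    sch <- build_schedule(trajectory_config("RADIAL2D", n, p))
    az <- sort(sch$azimuth_deg %% 180)
    gaps <- diff(c(az, az[1] + 180))
    expect_lt(max(gaps), phi * (180 / n) * 1.0001)
  }
})

test_that("per-kz-partition subsequences are generalized golden-angle sequences", {
  p <- sequence_params()
  for (pat in c("RSOS_PSI1", "RSOS_PSI9")) {
    sch <- build_schedule(trajectory_config(pat, 8, p))
    ord <- if (pat == "RSOS_PSI1") 1 else 9
    inc <- (9 * tiny_golden_angle(ord)) %% 360
    for (z in c(0, 4, 8)) {
      az <- sch$azimuth_deg[sch$kz_index == z]
      expect_equal(diff(az) %% 360, rep(inc, length(az) - 1), tolerance = 1e-9)
    }
  }
})

test_that("spoke coordinates span the Nyquist diameter with a centre sample", {
  p <- tiny_params()
  sch <- build_schedule(trajectory_config("ASOS", 3, p))
  co <- spoke_coordinates(sch, p)
  kr <- sqrt(co[, , 1]^2 + co[, , 2]^2)
  # exactly one zero-radius sample per spoke
  expect_equal(rowSums(kr == 0), rep(1, nrow(sch)))
  expect_equal(max(kr), p$matrix / 2, tolerance = 1e-9)
  expect_true(all(kr < p$matrix / 2 + 1e-9))
  # azimuth-0 spokes lie on the kx axis
  ev0 <- which(sch$azimuth_deg == 0)
  expect_true(all(abs(co[ev0, , 2]) < 1e-12))
  # kz partitions are centred integers
  expect_equal(sort(unique(as.vector(co[, , 3]))), c(-1, 0, 1))
})

test_that("frame binning reproduces the protocol frame rates", {
  p7 <- sequence_params(n_slices = 7)
  sch7 <- build_schedule(trajectory_config("ASOS", 402, p7))
  b7 <- bin_frames(sch7, 6)
  expect_equal(round(b7$frame_rate, 1), 6.2)
  expect_equal(b7$n_frames, 67L)  # floor(402 / 6)
  expect_equal(b7$frame_duration, 6 * 9 * 3.0e-3)
  p21 <- sequence_params(n_slices = 21)
  sch21 <- build_schedule(trajectory_config("ASOS", 12, p21))
  b21 <- bin_frames(sch21, 6)
  expect_equal(round(b21$frame_rate, 1), 2.1)
  # frames are contiguous blocks; trailing partial frame dropped
  expect_equal(sum(is.na(b7$frame_assignments)), 0L)
  sch7b <- build_schedule(trajectory_config("ASOS", 7, p7))
  b <- bin_frames(sch7b, 6)
  expect_equal(b$n_frames, 1L)
  expect_equal(sum(is.na(b$frame_assignments)), 9L)
  runs <- rle(b7$frame_assignments)
  expect_true(all(runs$lengths == 54))
  expect_error(bin_frames(sch7, 0))
})
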