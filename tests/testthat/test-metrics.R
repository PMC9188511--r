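test_that("bolus area and volume follow voxel arithmetic", {
  masks <- array(FALSE, dim = c(1, 5, 20, 20))
  masks[1, 3, 1:10, 1:10] <- TRUE  # 100 voxels in the middle slice
  av <- bolus_area_volume(masks, voxel_size = c(2, 2, 6), middle_slice = 3)
  expect_equal(av$area_cm2, 4.0)   # 100 x 0.04 cm^2
  expect_equal(av$volume_cm3, 100 * 0.024)
  # 833 voxels -> 20.0 cm^3 at one decimal
  m2 <- array(FALSE, dim = c(10, 20, 20))
  m2[seq_len(833)] <- TRUE
  av2 <- bolus_area_volume(m2, voxel_size = c(2, 2, 6), middle_slice = 5)
  expect_equal(round(av2$volume_cm3, 1), 20.0)
  expect_warning(av0 <- bolus_area_volume(array(FALSE, c(3, 4, 4))), "empty")
  expect_equal(av0, list(area_cm2 = 0, volume_cm3 = 0))
})

test_that("laryngeal elevation is the maximal displacement from rest", {
  static <- landmark_track(matrix(c(1, 2, 3), 5, 3, byrow = TRUE))
  expect_equal(laryngeal_elevation(static), 0)
  # monotone rise then fall: apex displacement
  pos <- cbind(0, c(0, -5, -12, -20, -9, 0), 0)
  tr <- landmark_track(pos, motion_state = c(TRUE, rep(FALSE, 4), TRUE),
                       frame_rate = 10)
  expect_equal(laryngeal_elevation(tr), 20)
  pos_na <- pos; pos_na[3, 2] <- NA
  expect_error(laryngeal_elevation(landmark_track(pos_na)), "missing")
})

test_that("submental contraction uses signed relative length change", {
  mand <- matrix(0, 4, 3)
  hyo <- cbind(c(20, 15, 20, 22), 0, 0)
  tr <- landmark_track(hyo * 0, mand, hyo,
                       motion_state = c(TRUE, FALSE, FALSE, TRUE),
                       frame_rate = 10)
  expect_equal(submental_contraction(tr), -25)  # 15/20 - 1
  # lengthening gives a positive sign
  tr2 <- landmark_track(hyo * 0, mand, cbind(c(20, 22, 20, 20), 0, 0),
                        motion_state = c(TRUE, FALSE, FALSE, TRUE),
                        frame_rate = 10)
  expect_equal(submental_contraction(tr2), 10)
  # static track: no change
  tr3 <- landmark_track(hyo * 0, mand, cbind(20, 0, 0)[rep(1, 4), ])
  expect_equal(submental_contraction(tr3), 0)
  expect_error(submental_contraction(landmark_track(hyo * 0, mand, mand)),
               "zero")
})

test_that("swallow duration counts first-swallow moving frames only", {
  expect_equal(swallow_duration(rep(TRUE, 10), 12.3), 0)
  flags <- c(rep(TRUE, 3), rep(FALSE, 27), rep(TRUE, 5))
  expect_equal(round(swallow_duration(flags, 12.3), 1), 2.2)
  # a second swallow after the return is excluded
  flags2 <- c(rep(TRUE, 3), rep(FALSE, 27), rep(TRUE, 2), rep(FALSE, 8), TRUE)
  expect_equal(swallow_duration(flags2, 12.3), swallow_duration(flags, 12.3))
  expect_warning(d <- swallow_duration(c(TRUE, FALSE, FALSE), 10), "series end")
  expect_equal(d, 0.2)
})

test_that("metrics computed from phantom ground truth equal the programmed values", {
  sc <- cached("dyn_scene", dynamic_swallow_phantom())
  tr <- as_landmark_track(sc)
  m <- swallow_metrics(tr)
  val <- function(name) m$value[m$metric == name]
  expect_equal(val("Laryngeal elevation (mm)"), 20)
  expect_equal(val("Contraction of submental muscles (%)"), -25)
  expect_equal(val("Bolus (cm3)"), 833 * 0.024)
  expect_equal(val("Bolus (cm3)"), 20, tolerance = 0.024)
  # duration equals the moving-frame count over the frame rate
  gt <- sc$ground_truth
  n_mov <- gt$swallow_offset - gt$swallow_onset + 1
  fr <- 1 / diff(sc$frame_times[1:2])
  expect_equal(val("Duration (s)"), n_mov / fr)
  # metrics are intensity-scale invariant (they use masks/landmarks only)
  expect_identical(swallow_metrics(tr), m)
})

test_that("blob tracking recovers the programmed motion from clean frames", {
  sc <- cached("dyn_scene", dynamic_swallow_phantom())
  gt <- sc$ground_truth
  ser <- starstack:::.image_series(sc$frames, 6.17, sc$frame_times,
                                   sequence_params(matrix = 64, n_slices = 7))
  # per-frame positions within one in-plane voxel (2 mm) of the analytic
  # track; the blob is voxelised, so sub-voxel wobble during fast motion
  # is expected
  lt <- track_blob(ser, gt$larynx_rest, radius_mm = 9)
  expect_lt(max(sqrt(rowSums((lt - gt$larynx_track)^2))), 2)
  tr <- landmark_track(lt,
                       track_blob(ser, gt$mandible_pos, radius_mm = 8),
                       track_blob(ser, gt$hyoid_rest, radius_mm = 8),
                       motion_state = gt$motion_state, frame_rate = 6.17)
  expect_equal(laryngeal_elevation(tr), 20, tolerance = 0.5)
  expect_equal(submental_contraction(tr), -25, tolerance = 1)
  # partial-volume integral volume estimate on the clean frames
  v <- estimate_bolus_volume(ser, 1, gt$bolus_rest_centre)
  expect_equal(v, 20, tolerance = 1)
})
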