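# Quantitative swallowing parameters. The measurement operations take
# landmark tracks and bolus masks as input (from phantom ground truth or
# user-supplied annotations); automated tracking helpers for reconstructed
# series are provided separately and used for closed-loop validation only.

#' Landmark track container
#'
#' @param most_inferior_thyroid `T x 3` mm positions of the most inferior
#'   point of the thyroid cartilage.
#' @param mandible_right_edge,hyoid_left_edge `T x 3` mm landmark positions
#'   bounding the submental muscle length.
#' @param bolus_masks logical `(T, z, y, x)` bolus delineations (optional).
#' @param motion_state logical per frame, `TRUE` = stationary.
#' @param frame_rate frames per second.
#' @return object of class `landmark_track`.
#' @export
landmark_track <- function(most_inferior_thyroid, mandible_right_edge = NULL,
                           hyoid_left_edge = NULL, bolus_masks = NULL,
                           motion_state = NULL, frame_rate = NA_real_) {
  t_n <- nrow(most_inferior_thyroid)
  if (!is.null(motion_state)) stopifnot(length(motion_state) == t_n)
  structure(list(most_inferior_thyroid = most_inferior_thyroid,
                 mandible_right_edge = mandible_right_edge,
                 hyoid_left_edge = hyoid_left_edge,
                 bolus_masks = bolus_masks, motion_state = motion_state,
                 frame_rate = frame_rate, n_frames = t_n),
            class = "landmark_track")
}

#' Ground-truth landmark track of a dynamic phantom
#'
#' @param scene a [dynamic_swallow_phantom()] scene.
#' @return a [landmark_track()] built from the scene's analytic ground truth.
#' @export
as_landmark_track <- function(scene) {
  stopifnot(inherits(scene, "phantom_scene"))
  gt <- scene$ground_truth
  fr <- if (length(scene$frame_times) > 1) {
    1 / diff(scene$frame_times[1:2])
  } else NA_real_
  landmark_track(gt$larynx_track, gt$mandible_track, gt$hyoid_track,
                 gt$bolus_masks, gt$motion_state, fr)
}

# frames belonging to the (first) swallow plus the pre-swallow reference
.swallow_window <- function(motion_state) {
  if (is.null(motion_state) || all(motion_state)) {
    return(list(reference = 1L, frames = integer(0)))
  }
  first_moving <- which(!motion_state)[1]
  ref <- max(first_moving - 1L, 1L)
  after <- which(motion_state & seq_along(motion_state) > first_moving)
  last <- if (length(after)) after[1] - 1L else length(motion_state)
  list(reference = ref, frames = first_moving:last)
}

#' Bolus area and volume
#'
#' Area is the middle-slice mask count times the in-plane voxel area; volume
#' is the total mask count times the voxel volume, both at the rest frame
#' before swallow onset.
#'
#' @param masks logical `(T, z, y, x)` (or a single `(z, y, x)` mask).
#' @param voxel_size mm triplet.
#' @param middle_slice 1-based slice index; defaults to the central slice.
#' @param frame 1-based rest-frame index (default 1).
#' @return list with `area_cm2` and `volume_cm3`; `(0, 0)` with a warning
#'   for an empty mask.
#' @export
bolus_area_volume <- function(masks, voxel_size = c(2, 2, 6),
                              middle_slice = NULL, frame = 1) {
  d <- dim(masks)
  m <- if (length(d) == 4) array(masks[frame, , , ], dim = d[2:4]) else masks
  if (is.null(middle_slice)) middle_slice <- floor(dim(m)[1] / 2) + 1L
  if (!any(m)) {
    warning("empty bolus mask")
    return(list(area_cm2 = 0, volume_cm3 = 0))
  }
  area <- sum(m[middle_slice, , ]) * voxel_size[1] * voxel_size[2] / 100
  vol <- sum(m) * prod(voxel_size) / 1000
  list(area_cm2 = area, volume_cm3 = vol)
}

#' Laryngeal elevation
#'
#' Largest Euclidean distance between the position of the most inferior
#' point of the thyroid cartilage before swallowing (the last stationary
#' frame) and its positions during the swallow.
#'
#' @param track a [landmark_track()].
#' @return elevation in mm (0 for a static track).
#' @export
laryngeal_elevation <- function(track) {
  stopifnot(inherits(track, "landmark_track"))
  pos <- track$most_inferior_thyroid
  if (anyNA(pos)) stop("landmark positions contain missing frames")
  win <- .swallow_window(track$motion_state)
  frames <- if (length(win$frames)) win$frames else seq_len(nrow(pos))
  ref <- pos[win$reference, ]
  d <- sqrt(rowSums((pos[frames, , drop = FALSE] -
                       base::matrix(ref, length(frames), 3, byrow = TRUE))^2))
  max(d)
}

#' Submental muscle contraction
#'
#' The submental length is the distance from the right edge of the mandible
#' to the left edge of the hyoid bone; the contraction is the change of the
#' minimal length during the swallow relative to the rest length, in percent
#' (negative = shortening).
#'
#' @param track a [landmark_track()] with both landmarks.
#' @return percent change in `(-100, 100)`.
#' @export
submental_contraction <- function(track) {
  stopifnot(inherits(track, "landmark_track"))
  if (is.null(track$mandible_right_edge) || is.null(track$hyoid_left_edge)) {
    stop("both mandible and hyoid landmarks are required")
  }
  len <- sqrt(rowSums((track$mandible_right_edge - track$hyoid_left_edge)^2))
  if (anyNA(len)) stop("landmark positions contain missing frames")
  win <- .swallow_window(track$motion_state)
  rest <- len[win$reference]
  if (rest == 0) stop("rest length is zero")
  frames <- if (length(win$frames)) win$frames else seq_along(len)
  dev <- len[frames] - rest
  100 * dev[which.max(abs(dev))] / rest
}

#' Swallow duration
#'
#' Counts the frames from the last stationary motion state until the oral
#' tract first returns to a stationary state, divided by the frame rate.
#' Additional swallows after the first return are not included.
#'
#' @param motion_state logical per frame, `TRUE` = stationary.
#' @param frame_rate frames per second.
#' @return duration in seconds (0 if every frame is stationary). If motion
#'   never returns to stationary the duration runs to the series end, with a
#'   warning.
#' @export
swallow_duration <- function(motion_state, frame_rate) {
  stopifnot(is.logical(motion_state), frame_rate > 0)
  if (all(motion_state)) return(0)
  first_moving <- which(!motion_state)[1]
  last_stat <- first_moving - 1L
  ret <- which(motion_state & seq_along(motion_state) > first_moving)
  if (!length(ret)) {
    warning("motion never returns to stationary; duration runs to series end")
    ret_idx <- length(motion_state) + 1L
  } else {
    ret_idx <- ret[1]
  }
  (ret_idx - last_stat - 1L) / frame_rate
}

#' All swallowing metrics of a track
#'
#' @param track a [landmark_track()] with masks and motion state.
#' @param voxel_size mm triplet.
#' @return data frame with one row per metric (`Duration (s)`,
#'   `Bolus (cm2)`, `Bolus (cm3)`, `Laryngeal elevation (mm)`,
#'   `Contraction of submental muscles (%)`) and a `value` column.
#' @export
swallow_metrics <- function(track, voxel_size = c(2, 2, 6)) {
  stopifnot(inherits(track, "landmark_track"))
  win <- .swallow_window(track$motion_state)
  av <- bolus_area_volume(track$bolus_masks, voxel_size, frame = win$reference)
  data.frame(
    metric = c("Duration (s)", "Bolus (cm2)", "Bolus (cm3)",
               "Laryngeal elevation (mm)",
               "Contraction of submental muscles (%)"),
    value = c(swallow_duration(track$motion_state, track$frame_rate),
              av$area_cm2, av$volume_cm3,
              laryngeal_elevation(track),
              submental_contraction(track)))
}

# ---- closed-loop measurement helpers for reconstructed series ----

.mm_axes <- function(d, voxel_size) {
  list(z = (seq_len(d[1]) - 1 - floor(d[1] / 2)) * voxel_size[3],
       y = (seq_len(d[2]) - 1 - d[2] / 2) * voxel_size[2],
       x = (seq_len(d[3]) - 1 - d[3] / 2) * voxel_size[1])
}

#' Track a bright blob through a reconstructed series
#'
#' Intensity-weighted centroid tracking inside a spherical search window
#' that follows the blob from frame to frame, used to recover landmark
#' trajectories from reconstructions of the digital phantom (it is not a
#' clinical segmentation tool). Weights are the squared intensity excess
#' over the window's 60th percentile.
#'
#' @param series an `image_series`.
#' @param init_mm starting position `(x, y, z)` mm (e.g. the rest position).
#' @param radius_mm search radius (default 10).
#' @param smooth odd window length of a per-axis running median applied to
#'   the track (default 1 = none); 3 suppresses single-frame artefact
#'   outliers without attenuating swallowing-speed motion.
#' @return `T x 3` matrix of mm positions.
#' @export
track_blob <- function(series, init_mm, radius_mm = 10, smooth = 1) {
  stopifnot(inherits(series, "image_series"))
  d <- dim(series$frames)
  ax <- .mm_axes(d[2:4], series$voxel_size)
  pos <- base::matrix(0, d[1], 3)
  cur <- init_mm
  zz <- array(rep(ax$z, d[3] * d[4]), dim = d[2:4])
  yy <- aperm(array(rep(ax$y, d[2] * d[4]), dim = c(d[3], d[2], d[4])), c(2, 1, 3))
  xx <- aperm(array(rep(ax$x, d[2] * d[3]), dim = c(d[4], d[2], d[3])), c(2, 3, 1))
  for (tix in seq_len(d[1])) {
    mag <- Mod(array(series$frames[tix, , , ], dim = d[2:4]))
    # mean-shift: re-centre the window within the frame so the estimate is
    # not dragged behind the blob during fast motion; the total within-frame
    # shift is capped at half the window radius so the tracker cannot climb
    # onto a brighter neighbouring structure
    start <- cur
    for (pass in 1:3) {
      d2 <- (xx - cur[1])^2 + (yy - cur[2])^2 + (zz - cur[3])^2
      win <- d2 <= radius_mm^2
      v <- mag[win]
      wgt <- pmax(v - quantile(v, 0.75), 0)^2
      if (sum(wgt) == 0) wgt <- v
      new <- c(sum(xx[win] * wgt), sum(yy[win] * wgt), sum(zz[win] * wgt)) /
        sum(wgt)
      step <- new - start
      len <- sqrt(sum(step^2))
      capped <- len > radius_mm / 2
      if (capped) new <- start + step * (radius_mm / 2) / len
      shift_sq <- sum((new - cur)^2)
      cur <- new
      if (capped || shift_sq < 0.25) break
    }
    pos[tix, ] <- cur
  }
  if (smooth > 1 && nrow(pos) >= smooth) {
    half <- (smooth - 1) %/% 2
    sm <- pos
    for (tix in seq_len(nrow(pos))) {
      idx <- max(1, tix - half):min(nrow(pos), tix + half)
      sm[tix, ] <- apply(pos[idx, , drop = FALSE], 2, median)
    }
    pos <- sm
  }
  pos
}

#' Partial-volume bolus volume estimate from a reconstruction
#'
#' Integrates the background-subtracted, plateau-normalised intensity over a
#' spherical region of interest:
#' `V = sum (I - tissue) / (bolus - tissue) * voxel_volume`. Because
#' blurring conserves the intensity integral, this estimator is unbiased
#' under the spatial smoothing a compressed-sensing reconstruction
#' introduces, unlike a thresholded voxel count. The tissue level is the
#' median intensity in a shell around the ROI; the bolus plateau level is
#' the median of the brightest decile inside the ROI.
#'
#' @param series an `image_series`.
#' @param frame 1-based frame index (use a rest frame).
#' @param centre_mm ROI centre `(x, y, z)` mm.
#' @param radius_mm ROI radius (default 28, generous around a 20 mL bolus).
#' @return estimated volume in mL (cm^3).
#' @export
estimate_bolus_volume <- function(series, frame, centre_mm, radius_mm = 28) {
  stopifnot(inherits(series, "image_series"))
  d <- dim(series$frames)
  ax <- .mm_axes(d[2:4], series$voxel_size)
  zz <- array(rep(ax$z, d[3] * d[4]), dim = d[2:4])
  yy <- aperm(array(rep(ax$y, d[2] * d[4]), dim = c(d[3], d[2], d[4])), c(2, 1, 3))
  xx <- aperm(array(rep(ax$x, d[2] * d[3]), dim = c(d[4], d[2], d[3])), c(2, 3, 1))
  mag <- Mod(array(series$frames[frame, , , ], dim = d[2:4]))
  d2 <- (xx - centre_mm[1])^2 + (yy - centre_mm[2])^2 + (zz - centre_mm[3])^2
  roi <- d2 <= radius_mm^2
  shell <- d2 > radius_mm^2 & d2 <= (radius_mm + 8)^2
  inside <- mag[roi]
  plateau <- median(inside[inside >= quantile(inside, 0.9)])
  # tissue level from the shell, excluding empty background voxels
  sh <- mag[shell]
  sh <- sh[sh > 0.15 * plateau]
  if (!length(sh)) stop("no tissue reference found around the ROI")
  tissue <- median(sh)
  if (plateau <= tissue) stop("no hyperintense bolus found in the ROI")
  frac <- pmax(inside - tissue, 0) / (plateau - tissue)
  sum(frac) * prod(series$voxel_size) / 1000
}
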