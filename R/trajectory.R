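#' Golden and tiny golden angles
#'
#' The tiny golden angles generalise the golden angle: `psi_N =
#' 180 / (tau + N - 1)` degrees, with `tau = (1 + sqrt(5))/2` the golden
#' ratio. `psi_1` is the classical golden angle (111.25 degrees at two
#' decimals); higher orders give smaller azimuthal jumps while retaining the
#' near-uniform spoke coverage that permits sliding-window reconstruction.
#'
#' @param order positive integer order `N` of the tiny golden angle.
#' @return angle in degrees.
#' @examples
#' tiny_golden_angle(1)  # 111.2461
#' tiny_golden_angle(9)  # 18.713
#' @export
tiny_golden_angle <- function(order) {
  if (length(order) != 1L || !is.numeric(order) || !is.finite(order) ||
      order < 1 || order != round(order)) {
    stop("`order` must be a single positive integer")
  }
  tau <- (1 + sqrt(5)) / 2
  180 / (tau + order - 1)
}

#' Sequence (readout) parameters
#'
#' Container for the pulse-sequence quantities the simulator needs. TE and
#' flip angle are carried as metadata only: the signal model is
#' proton-density-like and no relaxation contrast is simulated.
#'
#' @param tr repetition time per readout event, seconds.
#' @param te echo time, seconds (metadata only).
#' @param flip_angle degrees (metadata only).
#' @param n_readout samples per spoke (readout oversampling included).
#' @param matrix in-plane grid size.
#' @param n_slices prescribed slices (before slice oversampling).
#' @param oversampling_factor kz oversampling factor; the effective number of
#'   kz partitions is `round(oversampling_factor * n_slices)`.
#' @param voxel_size mm triplet (x, y, z).
#' @return object of class `sequence_params`.
#' @export
sequence_params <- function(tr = 3.0e-3, te = 1.26e-3, flip_angle = 10,
                            n_readout = 256, matrix = 128, n_slices = 7,
                            oversampling_factor = 1.28,
                            voxel_size = c(2, 2, 6)) {
  stopifnot(tr > 0, n_readout >= 2, n_slices >= 1, oversampling_factor >= 1,
            length(voxel_size) == 3, all(voxel_size > 0), matrix >= 2)
  n_kz <- as.integer(round(oversampling_factor * n_slices))
  if (n_kz < n_slices) stop("effective kz count must be >= n_slices")
  structure(
    list(tr = tr, te = te, flip_angle = flip_angle,
         n_readout = as.integer(n_readout), matrix = as.integer(matrix),
         n_slices = as.integer(n_slices),
         oversampling_factor = oversampling_factor,
         n_kz = n_kz, voxel_size = as.numeric(voxel_size)),
    class = "sequence_params")
}

#' Number of kz partitions
#' @param params a [sequence_params()] object.
#' @return integer count of kz partitions including slice oversampling.
#' @export
n_kz <- function(params) params$n_kz

.patterns <- c("RADIAL2D", "ASOS", "RSOS_GR", "RSOS_PSI1", "RSOS_PSI9")

#' Trajectory configuration
#'
#' @param pattern one of `"RADIAL2D"`, `"ASOS"`, `"RSOS_GR"`, `"RSOS_PSI1"`,
#'   `"RSOS_PSI9"`.
#' @param spokes_per_slice spokes acquired per kz partition.
#' @param sequence a [sequence_params()] object.
#' @param tiny_angle_order order N of the tiny golden angle used by
#'   `RSOS_PSI9`; defaults to the kz partition count so one full star
#'   accumulates close to one golden angle of rotation.
#' @return object of class `trajectory_config`.
#' @export
trajectory_config <- function(pattern, spokes_per_slice,
                              sequence = sequence_params(),
                              tiny_angle_order = NULL) {
  pattern <- match.arg(pattern, .patterns)
  stopifnot(spokes_per_slice >= 1)
  if (is.null(tiny_angle_order)) tiny_angle_order <- n_kz(sequence)
  if (tiny_angle_order < 1 || tiny_angle_order != round(tiny_angle_order)) {
    stop("`tiny_angle_order` must be a positive integer")
  }
  structure(
    list(pattern = pattern, spokes_per_slice = as.integer(spokes_per_slice),
         tiny_angle_order = as.integer(tiny_angle_order), sequence = sequence),
    class = "trajectory_config")
}

#' Build an ordered stack-of-stars spoke schedule
#'
#' Produces the ordered list of acquisition events for the requested sampling
#' pattern. One *star* is one pass over all kz partitions; within a star the
#' kz partitions are visited in linear ascending order (inner loop), and the
#' azimuthal increment continues seamlessly from the inner loop into the next
#' star (outer loop) for the rotated patterns.
#'
#' Patterns:
#' * `ASOS` - aligned: all events of star `s` share azimuth `s * psi_1`.
#' * `RSOS_PSI1` - continuous golden angle: event `n` has azimuth
#'   `n * psi_1`.
#' * `RSOS_PSI9` - continuous tiny golden angle `psi_order`.
#' * `RSOS_GR` - simulation-only comparator with uniform in-plane spacing
#'   `180/spokes_per_slice` within each kz partition and a per-partition
#'   offset `kz_index * (psi_1 / n_kz)` (documented convention; the original
#'   scheme depends on the spoke count and excludes sliding windows).
#' * `RADIAL2D` - single kz plane, golden-angle increments.
#'
#' @param config a [trajectory_config()] object.
#' @return a `spoke_schedule`: a data frame with columns `global_index`,
#'   `star_index`, `kz_index` (0-based), `azimuth_deg` in `[0, 360)` and
#'   `time_s = global_index * TR`, plus pattern metadata in attributes.
#' @export
build_schedule <- function(config) {
  stopifnot(inherits(config, "trajectory_config"))
  sq <- config$sequence
  nkz <- if (config$pattern == "RADIAL2D") 1L else n_kz(sq)
  s_per <- config$spokes_per_slice
  n_events <- s_per * nkz
  gi <- seq_len(n_events) - 1L
  star <- gi %/% nkz
  kz <- gi %% nkz
  psi1 <- tiny_golden_angle(1)
  az <- switch(config$pattern,
    RADIAL2D = (gi * psi1) %% 360,
    ASOS = (star * psi1) %% 360,
    RSOS_PSI1 = (gi * psi1) %% 360,
    RSOS_PSI9 = (gi * tiny_golden_angle(config$tiny_angle_order)) %% 360,
    RSOS_GR = (star * (180 / s_per) + kz * (psi1 / nkz)) %% 360
  )
  sched <- data.frame(global_index = gi, star_index = star, kz_index = kz,
                      azimuth_deg = az, time_s = gi * sq$tr)
  structure(sched,
            class = c("spoke_schedule", "data.frame"),
            pattern = config$pattern, n_kz = nkz,
            tiny_angle_order = config$tiny_angle_order,
            sequence = sq)
}

#' K-space sample coordinates of a schedule
#'
#' Each event contributes `n_readout` samples on a full diameter through the
#' in-plane k-space origin at the event's azimuth, spanning the half-open
#' Nyquist interval `[-matrix/2, matrix/2)` cycles/FOV, with exactly one
#' sample at in-plane k = 0. The kz coordinate is the integer partition
#' frequency `kz_index - floor(n_kz/2)`.
#'
#' @param schedule a `spoke_schedule`.
#' @param params a [sequence_params()] (defaults to the schedule's own).
#' @return array `(events, n_readout, 3)` of (kx, ky, kz) in cycles/FOV.
#' @export
spoke_coordinates <- function(schedule, params = NULL) {
  stopifnot(inherits(schedule, "spoke_schedule"))
  if (is.null(params)) params <- attr(schedule, "sequence")
  nro <- params$n_readout
  N <- params$matrix
  nkz <- attr(schedule, "n_kz")
  r <- (seq_len(nro) - 1 - nro / 2) * (N / nro)  # one sample exactly at 0
  th <- schedule$azimuth_deg * pi / 180
  kx <- outer(cos(th), r)
  ky <- outer(sin(th), r)
  kzv <- schedule$kz_index - floor(nkz / 2)
  kz <- base::matrix(rep(kzv, nro), nrow = nrow(schedule))
  out <- array(0, dim = c(nrow(schedule), nro, 3))
  out[, , 1] <- kx
  out[, , 2] <- ky
  out[, , 3] <- kz
  out
}

#' Bin schedule events into time frames
#'
#' Frames are contiguous non-overlapping blocks of
#' `spokes_per_slice_per_frame * n_kz` events in acquisition order; a
#' trailing partial frame is dropped.
#'
#' @param schedule a `spoke_schedule`.
#' @param spokes_per_slice_per_frame spokes per kz partition per frame
#'   (6 in the reference protocol, giving 6.2 fps at 9 kz partitions and
#'   2.1 fps at 27).
#' @return object of class `frame_binning` with `frame_assignments` (1-based
#'   frame index per event, `NA` for dropped trailing events),
#'   `frame_duration` (s), `frame_rate` (fps), `n_frames` and
#'   `events_per_frame`.
#' @export
bin_frames <- function(schedule, spokes_per_slice_per_frame) {
  stopifnot(inherits(schedule, "spoke_schedule"))
  if (spokes_per_slice_per_frame < 1) {
    stop("`spokes_per_slice_per_frame` must be >= 1")
  }
  nkz <- attr(schedule, "n_kz")
  sq <- attr(schedule, "sequence")
  epf <- as.integer(spokes_per_slice_per_frame) * nkz
  n_events <- nrow(schedule)
  n_frames <- n_events %/% epf
  assign <- rep(NA_integer_, n_events)
  idx <- seq_len(n_frames * epf)
  assign[idx] <- rep(seq_len(n_frames), each = epf)
  duration <- epf * sq$tr
  structure(
    list(frame_assignments = assign, frame_duration = duration,
         frame_rate = 1 / duration, n_frames = n_frames,
         events_per_frame = epf,
         spokes_per_slice_per_frame = as.integer(spokes_per_slice_per_frame)),
    class = "frame_binning")
}

#' @export
print.spoke_schedule <- function(x, ...) {
  cat(sprintf("<spoke_schedule> pattern=%s, %d events, %d kz partition(s)\n",
              attr(x, "pattern"), nrow(x), attr(x, "n_kz")))
  print.data.frame(head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("... %d more events\n", nrow(x) - 5L))
  invisible(x)
}

#' @export
print.frame_binning <- function(x, ...) {
  cat(sprintf("<frame_binning> %d frames of %d events, %.3f s/frame (%.1f fps)\n",
              x$n_frames, x$events_per_frame, x$frame_duration, x$frame_rate))
  invisible(x)
}
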