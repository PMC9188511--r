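# Digital phantoms standing in for the scanner data: a static textured
# "pineapple-like" object for image-quality experiments and a dynamic
# midsagittal swallowing scene with exhaustive ground truth. Slices are
# sagittal: x = anterior->posterior, y = superior->inferior, z = right->left
# (slice direction). Positions are in mm relative to the grid centre; voxel
# (z, y, x) (0-based) sits at ((x - N/2) * vx, (y - N/2) * vy,
# (z - floor(nz/2)) * vz).

.phantom_scene <- function(frames, frame_times, voxel_size, ground_truth,
                           seed = NA_integer_) {
  structure(list(frames = frames, frame_times = frame_times,
                 voxel_size = voxel_size, ground_truth = ground_truth,
                 seed = seed),
            class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<phantom_scene> %d frame(s), grid %dx%dx%d (z,y,x), voxel %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(x$voxel_size, collapse = "x")))
  invisible(x)
}

# mm coordinate arrays for a (nz, ny, nx) grid
.mm_coords <- function(nz, ny, nx, voxel_size) {
  zc <- (seq_len(nz) - 1 - floor(nz / 2)) * voxel_size[3]
  yc <- (seq_len(ny) - 1 - ny / 2) * voxel_size[2]
  xc <- (seq_len(nx) - 1 - nx / 2) * voxel_size[1]
  list(
    z = array(rep(zc, ny * nx), dim = c(nz, ny, nx)),
    y = aperm(array(rep(yc, nz * nx), dim = c(ny, nz, nx)), c(2, 1, 3)),
    x = aperm(array(rep(xc, nz * ny), dim = c(nx, nz, ny)), c(2, 3, 1))
  )
}

#' Static textured phantom
#'
#' An ellipsoidal body with fine internal texture (radial wedges, concentric
#' rings and voxel-level speckle) on a zero background, so that blurring
#' introduced by undersampling or regularisation produces a measurable SSIM
#' degradation. Deterministic given `texture_seed`.
#'
#' @param matrix in-plane grid size (>= 32).
#' @param n_kz number of slices of the (oversampled) grid.
#' @param texture_seed integer seed for the speckle texture.
#' @param voxel_size mm triplet.
#' @return a `phantom_scene` with a single frame; `ground_truth$support`
#'   holds the body mask.
#' @export
static_phantom <- function(matrix = 128, n_kz = 9, texture_seed = 1,
                           voxel_size = c(2, 2, 6)) {
  stopifnot(matrix >= 32, n_kz >= 1)
  N <- as.integer(matrix)
  nz <- as.integer(n_kz)
  g <- .mm_coords(nz, N, N, voxel_size)
  fov <- N * voxel_size[1]
  ax <- 0.35 * fov
  ay <- 0.40 * fov
  az <- max(0.40 * nz * voxel_size[3], voxel_size[3])
  rho <- sqrt((g$x / ax)^2 + (g$y / ay)^2 + (g$z / az)^2)
  body <- rho <= 1
  # soft (raised-cosine) edge over ~3 voxels and smoothed speckle keep the
  # object's spectrum essentially inside the radially sampled k-space disk,
  # so a Nyquist-sampled acquisition can represent it; background stays
  # exactly zero outside the ellipsoid
  env <- pmin(pmax((1 - rho) / 0.10, 0), 1)
  env <- env^2 * (3 - 2 * env)
  th <- atan2(g$y, g$x)
  r <- sqrt(g$x^2 + g$y^2)
  tex <- 0.8 + 0.22 * sin(10 * th) + 0.15 * sin(2 * pi * r / 11)
  set.seed(texture_seed)
  speck <- array(runif(nz * N * N, -1, 1), dim = c(nz, N, N))
  speck <- .gauss_filter3(speck, c(0, 1.2, 1.2))
  speck <- 0.28 * speck / max(sd(speck), 1e-12)
  vol <- pmax(tex + speck, 0.05) * env
  vol[!body] <- 0
  frames <- array(as.complex(vol), dim = c(1L, nz, N, N))
  .phantom_scene(frames, frame_times = 0, voxel_size = voxel_size,
                 ground_truth = list(support = body), seed = texture_seed)
}

# mask of exactly n_vox voxels nearest (mm metric) to a centre; deterministic
.nearest_voxel_mask <- function(grid_mm, centre, n_vox) {
  d2 <- (grid_mm$x - centre[1])^2 + (grid_mm$y - centre[2])^2 +
    (grid_mm$z - centre[3])^2
  ord <- order(as.vector(d2), seq_along(d2))
  m <- array(FALSE, dim = dim(d2))
  m[ord[seq_len(n_vox)]] <- TRUE
  m
}

.ellipsoid_mask <- function(grid_mm, centre, semi) {
  ((grid_mm$x - centre[1]) / semi[1])^2 +
    ((grid_mm$y - centre[2]) / semi[2])^2 +
    ((grid_mm$z - centre[3]) / semi[3])^2 <= 1
}

# piecewise-linear path through waypoints, u in [0, 1]
.path_point <- function(waypoints, u) {
  n <- nrow(waypoints)
  if (u <= 0) return(waypoints[1, ])
  if (u >= 1) return(waypoints[n, ])
  s <- u * (n - 1)
  i <- min(floor(s) + 1, n - 1)
  f <- s - (i - 1)
  (1 - f) * waypoints[i, ] + f * waypoints[i + 1, ]
}

#' Dynamic digital swallowing phantom
#'
#' A midsagittal head-and-neck scene in which a hyperintense fluid bolus
#' travels from the oral cavity through the pharynx into the oesophagus,
#' a laryngeal marker (the most inferior point of the thyroid cartilage)
#' translates superiorly by exactly `laryngeal_elevation_mm` at the peak of
#' the swallow, and the mandible-to-hyoid landmark distance (submental
#' muscle length) shortens by exactly `submental_contraction_pct` percent at
#' the peak. All ground-truth tracks, masks and motion-state flags are
#' recorded analytically, so the swallowing metrics can be validated in
#' closed loop.
#'
#' The bolus mask contains exactly `round(bolus_volume_ml / voxel_volume)`
#' voxels in every frame. The swallow occupies the interval from 20% of the
#' series to 20% + 2.2 s (bounded by the series end); frames outside it are
#' static ("stationary motion state").
#'
#' @param bolus_volume_ml swallowed bolus volume (default 20 mL, the
#'   administered volume in the reference protocol).
#' @param laryngeal_elevation_mm peak superior displacement of the laryngeal
#'   landmark (default 20 mm).
#' @param submental_contraction_pct peak change of the submental length in
#'   percent; negative = shortening (default -25).
#' @param duration_s series duration (default 5 s).
#' @param fps frame rate; default is the native rate of 6 spokes per slice
#'   per frame at the grid's kz count and TR 3 ms.
#' @param matrix,n_slices,oversampling_factor,voxel_size grid geometry.
#' @param seed seed for the static texture.
#' @return a `phantom_scene` whose `ground_truth` holds `bolus_masks`
#'   (t,z,y,x logical), `bolus_volume_ml`, `larynx_track` (t x 3 mm),
#'   `mandible_track`, `hyoid_track`, `submental_length_mm`, `motion_state`
#'   (`TRUE` = stationary), `swallow_onset`/`swallow_offset` frame indices
#'   and the landmark rest positions.
#' @export
dynamic_swallow_phantom <- function(bolus_volume_ml = 20,
                                    laryngeal_elevation_mm = 20,
                                    submental_contraction_pct = -25,
                                    duration_s = 5, fps = NULL,
                                    matrix = 64, n_slices = 7,
                                    oversampling_factor = 1.28,
                                    voxel_size = c(2, 2, 6), seed = 1) {
  stopifnot(duration_s > 0, bolus_volume_ml > 0,
            submental_contraction_pct > -100, submental_contraction_pct < 100)
  N <- as.integer(matrix)
  nz <- as.integer(round(oversampling_factor * n_slices))
  if (is.null(fps)) fps <- 1 / (6 * nz * 3.0e-3)
  stopifnot(fps > 0)
  fov <- N * voxel_size[1]
  if (fov < 120) stop("field of view too small for the swallowing anatomy (needs >= 120 mm)")

  larynx_rest <- c(-2, 34, 0)
  if (larynx_rest[2] - laryngeal_elevation_mm < -fov / 2 + 6) {
    stop("requested laryngeal elevation exceeds the field of view")
  }
  mandible_pos <- c(-42, -2, 0)
  hyoid_rest <- c(-14, 0, 0)
  # oral cavity -> pharynx -> oesophagus; kept posterior of the laryngeal
  # and submental markers so marker tracking stays unambiguous
  bolus_path <- rbind(c(-25, -28, 0), c(14, -24, 0), c(32, 2, 0), c(32, 30, 0))

  n_frames <- floor(duration_s * fps) + 1L
  times <- (seq_len(n_frames) - 1) / fps
  t0 <- 0.2 * duration_s
  t1 <- min(t0 + 2.2, 0.95 * duration_s)

  # motion profiles evaluated at frame times; bump normalised so the peak
  # displacement/contraction is hit exactly at one frame
  phase <- pmin(pmax((times - t0) / (t1 - t0), 0), 1)
  moving <- times > t0 & times < t1
  # raised bump saturated at 1 over the central fifth of the swallow: the
  # larynx is held elevated (and the submental muscles contracted) during
  # pharyngeal transit, so the peak is an exact plateau, not a single frame
  g <- ifelse(moving, pmin(sin(pi * phase)^2 / sin(0.4 * pi)^2, 1), 0)
  if (max(g) > 0) g <- g / max(g)
  u <- 3 * phase^2 - 2 * phase^3  # smoothstep bolus progress

  grid <- .mm_coords(nz, N, N, voxel_size)
  tissue <- .ellipsoid_mask(grid, c(0, 0, 0),
                            c(0.40 * fov, 0.44 * fov,
                              max(0.48 * n_slices * voxel_size[3], voxel_size[3])))
  set.seed(seed)
  tissue_tex <- array(0.4, dim = c(nz, N, N)) +
    array(runif(nz * N * N, -0.04, 0.04), dim = c(nz, N, N))

  voxel_ml <- prod(voxel_size) / 1000
  n_bolus <- round(bolus_volume_ml / voxel_ml)
  if (n_bolus < 1) stop("bolus volume below one voxel")

  frames <- array(0i, dim = c(n_frames, nz, N, N))
  bolus_masks <- array(FALSE, dim = c(n_frames, nz, N, N))
  larynx_track <- base::matrix(0, n_frames, 3)
  hyoid_track <- base::matrix(0, n_frames, 3)
  submental_len <- numeric(n_frames)
  dir_mh <- (hyoid_rest - mandible_pos)
  len_rest <- sqrt(sum(dir_mh^2))
  dir_mh <- dir_mh / len_rest

  for (tix in seq_len(n_frames)) {
    vol <- array(0, dim = c(nz, N, N))
    vol[tissue] <- tissue_tex[tissue]

    larynx <- larynx_rest - c(0, laryngeal_elevation_mm * g[tix], 0)
    larynx_track[tix, ] <- larynx
    lmask <- .ellipsoid_mask(grid, larynx, c(4.5, 5.5, 7))
    vol[lmask] <- 0.9

    len_t <- len_rest * (1 + submental_contraction_pct / 100 * g[tix])
    hyoid <- mandible_pos + dir_mh * len_t
    hyoid_track[tix, ] <- hyoid
    submental_len[tix] <- len_t
    vol[.ellipsoid_mask(grid, mandible_pos, c(4.5, 4.5, 6))] <- 0.9
    vol[.ellipsoid_mask(grid, hyoid, c(4.5, 4.5, 6))] <- 0.9

    centre <- .path_point(bolus_path, u[tix])
    bmask <- .nearest_voxel_mask(grid, centre, n_bolus)
    vol[bmask] <- 1.3
    bolus_masks[tix, , , ] <- bmask
    frames[tix, , , ] <- vol
  }

  onset <- if (any(moving)) which(moving)[1] else NA_integer_
  offset <- if (any(moving)) tail(which(moving), 1) else NA_integer_
  gt <- list(
    bolus_masks = bolus_masks,
    bolus_rest_centre = bolus_path[1, ],
    bolus_volume_ml = n_bolus * voxel_ml,
    larynx_track = larynx_track,
    mandible_track = base::matrix(mandible_pos, n_frames, 3, byrow = TRUE),
    hyoid_track = hyoid_track,
    submental_length_mm = submental_len,
    motion_state = !moving,  # TRUE = stationary
    swallow_onset = onset, swallow_offset = offset,
    larynx_rest = larynx_rest, mandible_pos = mandible_pos,
    hyoid_rest = hyoid_rest,
    programmed = list(bolus_volume_ml = bolus_volume_ml,
                      laryngeal_elevation_mm = laryngeal_elevation_mm,
                      submental_contraction_pct = submental_contraction_pct)
  )
  .phantom_scene(frames, times, voxel_size, gt, seed = seed)
}

#' Smooth complex coil sensitivity maps with noise covariance
#'
#' Emulates a receive array: coils arranged on a circle around the in-plane
#' FOV with Gaussian sensitivity falloff, per-coil complex phase ramps, and a
#' small common floor so the root-sum-of-squares stays bounded away from zero
#' over any object inside the FOV. The noise covariance is a random Hermitian
#' positive-definite matrix with off-diagonal coupling, unit mean diagonal.
#'
#' With `n_coils = 1` and `smoothness = Inf` the map is exactly constant
#' (identity coil) and SENSE degenerates to gridding.
#'
#' @param n_coils number of receive channels.
#' @param grid integer triplet `(n_kz, ny, nx)`.
#' @param smoothness falloff width as a fraction of the FOV half-width
#'   (default 0.8); `Inf` gives constant maps.
#' @param seed integer seed.
#' @return object of class `sensitivity_maps`: `maps` complex
#'   `(coil, z, y, x)` and `noise_covariance` (`n_coils x n_coils`).
#' @export
coil_sensitivities <- function(n_coils = 8, grid = c(9, 128, 128),
                               smoothness = 0.8, seed = 1) {
  stopifnot(n_coils >= 1, length(grid) == 3)
  nz <- grid[1]; ny <- grid[2]; nx <- grid[3]
  set.seed(seed)
  maps <- array(0i, dim = c(n_coils, nz, ny, nx))
  if (is.infinite(smoothness)) {
    maps[] <- 1 + 0i
  } else {
    g <- .mm_coords(nz, ny, nx, c(1, 1, 1))  # index units
    sigma <- smoothness * nx / 2
    for (c_i in seq_len(n_coils)) {
      ang <- 2 * pi * (c_i - 1) / n_coils
      cx <- 0.52 * nx * cos(ang)
      cy <- 0.52 * ny * sin(ang)
      cz <- 0.25 * nz * ((c_i %% 2) * 2 - 1)
      d2 <- (g$x - cx)^2 + (g$y - cy)^2 + ((g$z - cz) * (nx / max(nz, 1)))^2
      mag <- 0.15 + exp(-d2 / (2 * sigma^2))
      ph <- 2 * pi * (0.15 * runif(1, -1, 1) * g$x +
                      0.15 * runif(1, -1, 1) * g$y) / nx +
        runif(1, 0, 2 * pi)
      maps[c_i, , , ] <- mag * exp(1i * ph)
    }
  }
  a <- base::matrix(complex(real = rnorm(n_coils^2), imaginary = rnorm(n_coils^2)) /
                      sqrt(2), n_coils, n_coils)
  cov <- 0.5 * diag(n_coils) + 0.5 * (a %*% Conj(t(a))) / n_coils
  cov <- (cov + Conj(t(cov))) / 2
  d <- Re(diag(cov))
  cov <- cov / mean(d)
  structure(list(maps = maps, noise_covariance = cov),
            class = "sensitivity_maps")
}

#' @export
print.sensitivity_maps <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("<sensitivity_maps> %d coil(s), grid %dx%dx%d\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}
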