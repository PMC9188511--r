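# Compressed-sensing reconstruction: locally low-rank regularisation in
# plane plus total variation over time, solved by a proximal-gradient scheme
# with alternating proximal operators.

#' Reconstruction configuration
#'
#' @param lambda_llr locally-low-rank regularisation weight (default 0.001,
#'   on data normalised so the peak gridded image magnitude is 1).
#' @param lambda_tv_time temporal total-variation weight (default 0.005).
#' @param llr_patch in-plane patch edge in voxels (default 8); patches are
#'   cycled by a random seeded shift each outer iteration.
#' @param iterations outer proximal-gradient iterations (default 30).
#' @param tolerance relative objective-change stopping tolerance
#'   (default 1e-4).
#' @param spokes_per_slice_per_frame frame binning (default 6).
#' @param sliding_window logical; see [sliding_window()].
#' @param seed seed for the patch-shift randomisation.
#' @return object of class `recon_config`.
#' @export
recon_config <- function(lambda_llr = 0.001, lambda_tv_time = 0.005,
                         llr_patch = 8, iterations = 30, tolerance = 1e-4,
                         spokes_per_slice_per_frame = 6,
                         sliding_window = FALSE, seed = 1) {
  stopifnot(lambda_llr >= 0, lambda_tv_time >= 0, llr_patch >= 2,
            iterations >= 1, spokes_per_slice_per_frame >= 1)
  structure(list(lambda_llr = lambda_llr, lambda_tv_time = lambda_tv_time,
                 llr_patch = as.integer(llr_patch),
                 iterations = as.integer(iterations), tolerance = tolerance,
                 spokes_per_slice_per_frame = as.integer(spokes_per_slice_per_frame),
                 sliding_window = isTRUE(sliding_window),
                 seed = as.integer(seed)),
            class = "recon_config")
}

# singular-value soft threshold of the Casorati matrix (space x time) of
# each in-plane patch, per slice, with cyclic shift (sy, sx).
# frames: (T, nz, N, N); returns same shape and the summed nuclear norm
.llr_prox <- function(frames, thresh, patch, shift = c(0L, 0L)) {
  d <- dim(frames)
  Tn <- d[1]; nz <- d[2]; N <- d[3]
  nuc <- 0
  for (z in seq_len(nz)) {
    sl <- aperm(array(frames[, z, , ], dim = c(Tn, N, N)), c(2, 3, 1)) # (y,x,T)
    iy <- ((seq_len(N) - 1 + shift[1]) %% N) + 1L
    ix <- ((seq_len(N) - 1 + shift[2]) %% N) + 1L
    sl <- sl[iy, ix, , drop = FALSE]
    y0 <- seq(1, N, by = patch)
    for (py in y0) {
      ys <- py:min(py + patch - 1, N)
      for (px in y0) {
        xs <- px:min(px + patch - 1, N)
        blk <- sl[ys, xs, , drop = FALSE]
        M <- base::matrix(blk, nrow = length(ys) * length(xs), ncol = Tn)
        sv <- La.svd(M)
        s_thr <- pmax(sv$d - thresh, 0)
        nuc <- nuc + sum(s_thr)
        Mt <- sv$u %*% (s_thr * sv$vt)
        sl[ys, xs, ] <- array(Mt, dim = dim(blk))
      }
    }
    inv_y <- order(iy); inv_x <- order(ix)
    frames[, z, , ] <- aperm(sl[inv_y, inv_x, , drop = FALSE], c(3, 1, 2))
  }
  list(frames = frames, nuclear = nuc)
}

# nuclear norm of the current partition without thresholding
.llr_norm <- function(frames, patch, shift = c(0L, 0L)) {
  .llr_prox(frames, 0, patch, shift)$nuclear
}

# temporal TV prox applied to real and imaginary parts voxelwise
.tv_time_prox <- function(frames, thresh) {
  d <- dim(frames)
  m <- base::matrix(frames, nrow = d[1])
  re <- .tv1d_prox_cols(Re(m), thresh)
  im <- .tv1d_prox_cols(Im(m), thresh)
  array(complex(real = re, imaginary = im), dim = d)
}

.tv_time_norm <- function(frames) {
  d <- dim(frames)
  if (d[1] < 2) return(0)
  m <- base::matrix(frames, nrow = d[1])
  df <- m[-1, , drop = FALSE] - m[-d[1], , drop = FALSE]
  sum(abs(Re(df))) + sum(abs(Im(df)))
}

#' Compressed-sensing dynamic reconstruction
#'
#' Minimises
#' `0.5 ||W^(1/2) (E x - y)||^2 + lambda_llr * sum_patches ||Casorati||_* +
#' lambda_tv * ||grad_t x||_1`
#' by proximal gradient descent with alternating proximal operators
#' (singular-value soft-thresholding of space-time patch matrices, exact 1D
#' temporal-TV prox), with the ramp density compensation `W` as a
#' preconditioner of the data term. The data are normalised so the peak
#' magnitude of the initial gridded series is 1, which fixes the scale the
#' default regularisation weights (0.001 / 0.005) refer to. The step size is
#' set by power iteration on the normal operator and halved whenever the
#' objective increases; the objective log is returned.
#'
#' @param data a `kspace_data`.
#' @param binning a [bin_frames()] result for the data's schedule.
#' @param maps a `sensitivity_maps` object.
#' @param config a [recon_config()].
#' @return an `image_series` with `binning$n_frames` frames at
#'   `binning$frame_rate` fps; `$objective` holds the per-iteration
#'   objective, `$provenance$converged` the tolerance flag.
#' @export
cs_recon <- function(data, binning, maps, config = recon_config()) {
  stopifnot(inherits(data, "kspace_data"), inherits(binning, "frame_binning"),
            inherits(maps, "sensitivity_maps"),
            inherits(config, "recon_config"))
  params <- data$params
  sched <- data$schedule
  m <- .effective_maps(data, maps)
  w <- .radial_dcf(params)
  w <- w / mean(w)  # unit-mean: fidelity on the per-sample counting scale
  Tn <- binning$n_frames
  if (Tn < 1) stop("binning contains no complete frame")
  frames_ev <- lapply(seq_len(Tn), function(f) {
    which(!is.na(binning$frame_assignments) & binning$frame_assignments == f)
  })
  subs <- lapply(frames_ev, function(ev) .subset_schedule(sched, ev))
  ys <- lapply(frames_ev, function(ev) data$samples[ev, , , drop = FALSE])

  nkz <- attr(sched, "n_kz")
  N <- params$matrix
  x <- array(0i, dim = c(Tn, nkz, N, N))
  for (f in seq_len(Tn)) {
    x[f, , , ] <- .sense_adjoint(ys[[f]], subs[[f]], params, m, weights = w)
  }
  # fit a global scalar so the gridded initialisation sits at the
  # least-squares amplitude of the data, then normalise the series to unit
  # peak magnitude (the scale the default lambdas refer to)
  num <- 0; den <- 0
  for (f in seq_len(Tn)) {
    e0 <- .sense_forward(array(x[f, , , ], dim = c(nkz, N, N)),
                         subs[[f]], params, m)
    wmat <- base::matrix(w, nrow = dim(e0)[1], ncol = dim(e0)[2], byrow = TRUE)
    for (ch in seq_len(dim(e0)[3])) {
      num <- num + sum(wmat * Re(Conj(e0[, , ch]) * ys[[f]][, , ch]))
      den <- den + sum(wmat * Mod(e0[, , ch])^2)
    }
  }
  alpha <- if (den > 0) num / den else 1
  x <- alpha * x
  scale <- max(Mod(x))
  if (scale == 0) scale <- 1
  x <- x / scale
  ys <- lapply(ys, function(y) y / scale)

  # Lipschitz estimate of E^H W E by power iteration on the first frame
  set.seed(config$seed)
  v <- array(complex(real = rnorm(nkz * N * N), imaginary = rnorm(nkz * N * N)),
             dim = c(nkz, N, N))
  v <- v / sqrt(sum(Mod(v)^2))
  L <- 1
  for (i in 1:8) {
    av <- .sense_adjoint(.sense_forward(v, subs[[1]], params, m),
                         subs[[1]], params, m, weights = w)
    L <- sqrt(sum(Mod(av)^2))
    if (L == 0) { L <- 1; break }
    v <- av / L
  }
  step <- 1 / (1.05 * L)

  objective <- function(xc, shift) {
    fid <- 0
    for (f in seq_len(Tn)) {
      r <- .sense_forward(array(xc[f, , , ], dim = c(nkz, N, N)),
                          subs[[f]], params, m) - ys[[f]]
      wr <- sweep(Mod(r)^2, 2, w, `*`)
      fid <- fid + 0.5 * sum(wr)
    }
    fid + config$lambda_llr * .llr_norm(xc, config$llr_patch, shift) +
      config$lambda_tv_time * .tv_time_norm(xc)
  }

  grad_fun <- function(xc) {
    grad <- array(0i, dim = dim(xc))
    for (f in seq_len(Tn)) {
      r <- .sense_forward(array(xc[f, , , ], dim = c(nkz, N, N)),
                          subs[[f]], params, m) - ys[[f]]
      grad[f, , , ] <- .sense_adjoint(r, subs[[f]], params, m, weights = w)
    }
    grad
  }
  prox_fun <- function(xc, shift) {
    if (config$lambda_llr > 0) {
      xc <- .llr_prox(xc, step * config$lambda_llr, config$llr_patch,
                      shift)$frames
    }
    if (config$lambda_tv_time > 0 && Tn > 1) {
      xc <- .tv_time_prox(xc, step * config$lambda_tv_time)
    }
    xc
  }

  # FISTA with adaptive restart; steps are only accepted when the objective
  # decreases, so the logged objective is non-increasing
  obj_log <- objective(x, c(0L, 0L))
  converged <- FALSE
  z <- x
  tk <- 1
  for (it in seq_len(config$iterations)) {
    shift <- c(sample.int(config$llr_patch, 1) - 1L,
               sample.int(config$llr_patch, 1) - 1L)
    accepted <- FALSE
    for (try in 1:3) {
      xn <- prox_fun(z - step * grad_fun(z), shift)
      obj_new <- objective(xn, shift)
      if (obj_new <= tail(obj_log, 1) * (1 + 1e-12)) {
        accepted <- TRUE
        break
      }
      # restart momentum at the last accepted iterate; then shrink the step
      if (try == 1 && tk > 1) {
        z <- x
        tk <- 1
      } else {
        step <- step / 2
        z <- x
        tk <- 1
      }
    }
    if (!accepted) break
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- xn + ((tk - 1) / t_new) * (xn - x)
    x <- xn
    tk <- t_new
    prev <- tail(obj_log, 1)
    obj_log <- c(obj_log, obj_new)
    if (is.finite(prev) && abs(prev - obj_new) <= config$tolerance * abs(prev)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("cs_recon reached the iteration cap without meeting the objective tolerance")
  }

  # frame timestamps at acquisition midpoints
  mids <- vapply(frames_ev, function(ev) mean(sched$time_s[ev]), numeric(1))
  out <- .image_series(x * scale, frame_rate = binning$frame_rate,
                       frame_times = mids, params = params,
                       objective = obj_log,
                       provenance = list(config = config,
                                         pattern = attr(sched, "pattern"),
                                         scale = scale,
                                         converged = converged))
  out
}

#' Sliding-window reconstruction
#'
#' Repeats the compressed-sensing reconstruction twice, independently, with
#' the second run's frame bins offset by half a frame of events, then
#' interleaves the frames of the two runs by acquisition midpoint time. Each
#' output frame is exactly one frame of one run (no blending); the output
#' frame rate is twice the base rate (12 fps at the native 6.2 fps of the
#' 7-slice protocol).
#'
#' @param data a `kspace_data`; `RSOS_GR` schedules are rejected because
#'   that comparator's spoke angles depend on the spoke count, which is
#'   incompatible with a sliding window.
#' @param binning base [bin_frames()] result.
#' @param maps a `sensitivity_maps` object.
#' @param config a [recon_config()].
#' @return an `image_series` with `2 * n_frames - 1` frames at twice the
#'   base frame rate.
#' @export
sliding_window <- function(data, binning, maps, config = recon_config()) {
  stopifnot(inherits(data, "kspace_data"), inherits(binning, "frame_binning"))
  if (attr(data$schedule, "pattern") == "RSOS_GR") {
    stop("RSOS_GR is not compatible with a sliding-window reconstruction")
  }
  run1 <- cs_recon(data, binning, maps, config)
  half <- binning$events_per_frame %/% 2L
  n_ev <- nrow(data$schedule)
  if (n_ev - half < binning$events_per_frame) {
    stop("fewer events than one full frame after the half-frame offset")
  }
  keep <- (half + 1L):n_ev
  data2 <- data
  data2$samples <- data$samples[keep, , , drop = FALSE]
  data2$coords <- data$coords[keep, , , drop = FALSE]
  data2$schedule <- .subset_schedule(data$schedule, keep)
  data2$meta$event_shifts <- data$meta$event_shifts[keep]
  binning2 <- bin_frames(data2$schedule, binning$spokes_per_slice_per_frame)
  run2 <- cs_recon(data2, binning2, maps, config)

  t1 <- run1$frame_times
  t2 <- run2$frame_times
  all_t <- c(t1, t2)
  src <- c(rep(1L, length(t1)), rep(2L, length(t2)))
  idx <- c(seq_along(t1), seq_along(t2))
  ord <- order(all_t)
  d <- dim(run1$frames)
  out <- array(0i, dim = c(length(all_t), d[2], d[3], d[4]))
  for (k in seq_along(ord)) {
    i <- ord[k]
    out[k, , , ] <- if (src[i] == 1L) run1$frames[idx[i], , , ]
                    else run2$frames[idx[i], , , ]
  }
  .image_series(out, frame_rate = 2 * binning$frame_rate,
                frame_times = all_t[ord], params = data$params,
                objective = run1$objective,
                provenance = list(config = config, sliding_window = TRUE,
                                  pattern = attr(data$schedule, "pattern")))
}

#' Flat-field correction
#'
#' Divides a magnitude volume by its own wide-Gaussian-blurred copy, removing
#' smooth coil-intensity shading: the result is dimensionless and close to 1
#' in homogeneous regions. A floor of `1e-3 * max(blurred)` guards the zero
#' background.
#'
#' @param vol 3D magnitude array `(z, y, x)`.
#' @param kernel_width_mm Gaussian sigma in mm (default 32; "wide" relative
#'   to the 2 mm in-plane voxels).
#' @param voxel_size mm triplet.
#' @return flat-fielded volume of the same shape, free of NaN/Inf.
#' @export
flat_field <- function(vol, kernel_width_mm = 32, voxel_size = c(2, 2, 6)) {
  stopifnot(length(dim(vol)) == 3)
  vol <- Mod(vol)
  if (max(vol) == 0) stop("flat_field: image is identically zero")
  sigma_vox <- kernel_width_mm / voxel_size[c(3, 2, 1)]  # (z,y,x) order
  blur <- .gauss_filter3(vol, sigma_vox)
  eps <- 1e-3 * max(blur)
  vol / (blur + eps)
}
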