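# Preprocessing and linear (CG-SENSE) reconstruction.

# multiply volumes (nz,ny,nx) by coil maps (coil,nz,ny,nx) -> (nz,ny,nx,coil)
.apply_maps <- function(vol, maps_znyxc) {
  array(as.vector(vol) * as.vector(maps_znyxc), dim = dim(maps_znyxc))
}

# coil-combine: sum_c conj(map_c) * img_c ; imgs (nz,ny,nx,coil)
.combine_coils <- function(imgs, maps_znyxc) {
  d <- dim(imgs)
  out <- array(0i, dim = d[1:3])
  for (ch in seq_len(d[4])) {
    out <- out + Conj(array(maps_znyxc[, , , ch], dim = d[1:3])) *
      array(imgs[, , , ch], dim = d[1:3])
  }
  out
}

#' Noise pre-whitening
#'
#' Transforms the coil dimension so that the residual noise covariance is the
#' identity: `samples_white = samples %*% t(C^(-1/2))` with `C` the stored
#' Hermitian positive-definite noise covariance. The whitening matrix is
#' recorded in `meta$whitening`; reconstruction functions apply the same
#' transform to the sensitivity maps so the signal model stays consistent.
#'
#' @param data a `kspace_data`.
#' @return the whitened `kspace_data` (noise covariance = identity).
#' @export
prewhiten <- function(data) {
  stopifnot(inherits(data, "kspace_data"))
  C <- data$noise_covariance
  C <- (C + Conj(t(C))) / 2
  e <- eigen(C, symmetric = TRUE)
  tol <- 1e-10 * max(e$values)
  if (min(e$values) <= tol) {
    stop(sprintf(paste0("noise covariance is singular or not positive ",
                        "definite (min eigenvalue %.3e); cannot whiten"),
                 min(e$values)))
  }
  W <- e$vectors %*% diag(1 / sqrt(e$values), nrow = length(e$values)) %*%
    Conj(t(e$vectors))
  d <- dim(data$samples)
  flat <- base::matrix(data$samples, ncol = d[3])
  data$samples <- array(flat %*% t(W), dim = d)
  prev <- data$meta$whitening
  data$meta$whitening <- if (is.null(prev)) W else W %*% prev
  data$noise_covariance <- diag(d[3]) + 0i
  data
}

# whiten maps consistently with prewhitened data
.effective_maps <- function(data, maps) {
  m <- maps$maps
  W <- data$meta$whitening
  if (!is.null(W)) {
    d <- dim(m)
    flat <- base::matrix(aperm(m, c(2, 3, 4, 1)), ncol = d[1])
    m <- aperm(array(flat %*% t(W), dim = c(d[2:4], d[1])), c(4, 1, 2, 3))
  }
  aperm(m, c(2, 3, 4, 1))  # (z,y,x,coil)
}

#' Gradient-delay (radial phase shift) correction
#'
#' Estimates a global readout shift from the phase slope of cross-spectra of
#' approximately opposed spoke pairs, and removes it by the corresponding
#' sinc (FFT phase-ramp) shift of every spoke. For an ideal radial
#' acquisition the opposed spoke is the reversed readout of its partner; a
#' gradient delay of `d` samples offsets the pair by `2d`.
#'
#' @param data a `kspace_data`.
#' @param tol_deg pairing tolerance on |azimuth difference - 180| (degrees).
#' @param max_pairs cap on the number of pairs used for the estimate.
#' @return corrected `kspace_data` with `meta$estimated_delay_samples` set.
#'   If no opposed pairs exist within tolerance the data are returned
#'   unchanged with a warning.
#' @export
gradient_delay_correct <- function(data, tol_deg = 2, max_pairs = 200) {
  stopifnot(inherits(data, "kspace_data"))
  az <- data$schedule$azimuth_deg
  n_ev <- length(az)
  nro <- dim(data$samples)[2]
  # pair each event with the closest-to-opposed partner
  pairs <- NULL
  used <- rep(FALSE, n_ev)
  ord <- order(az)
  az_s <- az[ord]
  for (i in seq_len(n_ev)) {
    if (used[i]) next
    target <- (az[i] + 180) %% 360
    j <- ord[which.min(pmin(abs(az_s - target), 360 - abs(az_s - target)))]
    dd <- abs(az[j] - target)
    dd <- min(dd, 360 - dd)
    if (j != i && !used[j] && dd <= tol_deg) {
      pairs <- rbind(pairs, c(i, j))
      used[i] <- used[j] <- TRUE
    }
    if (!is.null(pairs) && nrow(pairs) >= max_pairs) break
  }
  if (is.null(pairs)) {
    warning("no opposed spoke pairs within tolerance; correction skipped")
    data$meta$estimated_delay_samples <- NA_real_
    return(data)
  }
  n_coils <- dim(data$samples)[3]
  xs <- numeric(0)
  acc <- 0i
  for (p in seq_len(nrow(pairs))) {
    for (ch in seq_len(n_coils)) {
      f <- data$samples[pairs[p, 1], , ch]
      g <- rev(data$samples[pairs[p, 2], , ch])
      Fc <- fft(f)
      Gc <- fft(g)
      X <- Fc * Conj(Gc)
      # accumulated product of consecutive cross-spectrum bins: its phase is
      # the mean slope 2*pi*(relative shift)/nro per bin
      acc <- acc + sum(X[-1] * Conj(X[-nro]))
    }
  }
  rel_shift <- Arg(acc) * nro / (2 * pi)  # = 2*delay - 1 (index reversal offset)
  delay <- (rel_shift + 1) / 2
  data$samples <- .shift_readout(data$samples, -delay)
  data$meta$estimated_delay_samples <- delay
  data
}

# fractional readout shift of all spokes by `shift` samples (FFT phase ramp)
.shift_readout <- function(samples, shift) {
  d <- dim(samples)
  nro <- d[2]
  m <- ((seq_len(nro) - 1 + floor(nro / 2)) %% nro) - floor(nro / 2)  # centred freqs
  ramp <- exp(-2i * pi * m * shift / nro)
  out <- samples
  for (ch in seq_len(d[3])) {
    sp <- t(base::matrix(samples[, , ch], nrow = d[1]))  # readout x events
    sp <- mvfft(mvfft(sp) * ramp, inverse = TRUE) / nro
    out[, , ch] <- t(sp)
  }
  out
}

#' Estimate coil sensitivity maps from central k-space
#'
#' Low-resolution per-coil images are reconstructed by density-compensated
#' adjoint gridding of the central `lowres_fraction` of each readout, and
#' normalised by their root-sum-of-squares. Sensitivities are assumed
#' constant over time: a single estimate serves all frames.
#'
#' @param data a `kspace_data` (all spokes).
#' @param lowres_fraction fraction of the in-plane Nyquist radius kept
#'   (default 0.15).
#' @return a `sensitivity_maps` object (noise covariance copied from the
#'   data).
#' @export
estimate_sensitivities <- function(data, lowres_fraction = 0.15) {
  stopifnot(inherits(data, "kspace_data"))
  params <- data$params
  nro <- params$n_readout
  N <- params$matrix
  dr <- N / nro
  r <- (seq_len(nro) - 1 - nro / 2) * dr
  rmax <- lowres_fraction * N / 2
  w <- .radial_dcf(params) * exp(-0.5 * (r / (rmax / 2))^2) * (abs(r) <= rmax)
  vols <- .sos_adjoint(data$samples, data$schedule, params, weights = w)
  d <- dim(vols)
  rsos <- array(0, dim = d[1:3])
  for (ch in seq_len(d[4])) {
    rsos <- rsos + Mod(array(vols[, , , ch], dim = d[1:3]))^2
  }
  rsos <- sqrt(rsos)
  eps <- 1e-3 * max(rsos)
  maps <- array(0i, dim = c(d[4], d[1:3]))
  for (ch in seq_len(d[4])) {
    maps[ch, , , ] <- array(vols[, , , ch], dim = d[1:3]) / (rsos + eps)
  }
  structure(list(maps = maps, noise_covariance = data$noise_covariance),
            class = "sensitivity_maps")
}

# E and E^H for one event subset (SENSE encoding with the gridding NUFFT)
.sense_forward <- function(vol, sched, params, maps_znyxc) {
  .sos_forward(.apply_maps(vol, maps_znyxc), sched, params)
}

.sense_adjoint <- function(samples, sched, params, maps_znyxc, weights = NULL) {
  imgs <- .sos_adjoint(samples, sched, params, weights = weights)
  .combine_coils(imgs, maps_znyxc)
}

#' Fully sampled CG-SENSE reference reconstruction
#'
#' Conjugate-gradient solution of the density-weighted normal equations
#' `E^H W E x = E^H W y`, where `E` is the multi-coil stack-of-stars
#' encoding operator and `W` the ramp density compensation. Converges in a
#' handful of iterations at or above the Nyquist spoke count.
#'
#' @param data a `kspace_data` at/above the Nyquist spoke count.
#' @param maps a `sensitivity_maps` object.
#' @param tol relative residual tolerance (default 1e-5).
#' @param max_iter iteration cap (default 30).
#' @return an `image_series` with one frame; the iteration log (relative
#'   residuals) is stored in `$objective`.
#' @export
reference_recon <- function(data, maps, tol = 1e-5, max_iter = 30) {
  stopifnot(inherits(data, "kspace_data"), inherits(maps, "sensitivity_maps"))
  params <- data$params
  sched <- data$schedule
  m <- .effective_maps(data, maps)
  w <- .radial_dcf(params)
  rhs <- .sense_adjoint(data$samples, sched, params, m, weights = w)
  normal_op <- function(x) {
    .sense_adjoint(.sense_forward(x, sched, params, m), sched, params, m,
                   weights = w)
  }
  x <- array(0i, dim = dim(rhs))
  r <- rhs
  p <- r
  rs <- sum(Mod(r)^2)
  rhs_norm <- sqrt(sum(Mod(rhs)^2))
  if (rhs_norm == 0) {
    return(.image_series(array(0i, c(1L, dim(rhs))), frame_rate = NA_real_,
                         frame_times = 0, params = params,
                         objective = numeric(0)))
  }
  log_res <- numeric(0)
  for (it in seq_len(max_iter)) {
    ap <- normal_op(p)
    alpha <- rs / Re(sum(Conj(p) * ap))
    if (!is.finite(alpha)) stop("CG-SENSE diverged (non-finite step)")
    x <- x + alpha * p
    r <- r - alpha * ap
    rs_new <- sum(Mod(r)^2)
    rel <- sqrt(rs_new) / rhs_norm
    log_res <- c(log_res, rel)
    if (!is.finite(rel) || rel > 1e6) {
      stop(paste0("CG-SENSE diverged; residual log: ",
                  paste(sprintf("%.3g", log_res), collapse = ", ")))
    }
    if (rel < tol) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  .image_series(array(x, dim = c(1L, dim(x))), frame_rate = NA_real_,
                frame_times = 0, params = params, objective = log_res)
}

# image-series container shared by the reconstruction functions
.image_series <- function(frames, frame_rate, frame_times, params,
                          objective = NULL, provenance = list()) {
  structure(list(frames = frames, frame_rate = frame_rate,
                 frame_times = frame_times,
                 voxel_size = params$voxel_size, params = params,
                 objective = objective, provenance = provenance),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$frames)
  fr <- if (is.finite(x$frame_rate)) sprintf("%d fps", floor(x$frame_rate))
        else "static"
  cat(sprintf("<image_series> %d frame(s) of %dx%dx%d (z,y,x), %s\n",
              d[1], d[2], d[3], d[4], fr))
  invisible(x)
}
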