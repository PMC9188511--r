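# Image-quality evaluation: SSIM against the fully sampled reference.

.gauss_filter2 <- function(m, sigma) {
  .gauss_filter_dim(.gauss_filter_dim(m, 1, sigma), 2, sigma)
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM of two magnitude images with a Gaussian weighting window
#' (sigma 1.5, truncated at 4 sigma) and the standard constants K1 = 0.01,
#' K2 = 0.03. The local map is averaged after cropping the window radius at
#' the borders.
#'
#' @param reference,test magnitude matrices of identical shape.
#' @param sigma Gaussian window sigma in pixels (default 1.5).
#' @param data_range dynamic range `L`; defaults to `max(reference)`.
#' @param K1,K2 stabilisation constants.
#' @return scalar in `[-1, 1]`; `ssim(x, x)` is exactly 1.
#' @export
ssim <- function(reference, test, sigma = 1.5, data_range = NULL,
                 K1 = 0.01, K2 = 0.03) {
  reference <- Mod(as.matrix(reference))
  test <- Mod(as.matrix(test))
  if (!all(dim(reference) == dim(test))) {
    stop("`reference` and `test` must have identical shape")
  }
  if (is.null(data_range)) data_range <- max(reference)
  if (data_range <= 0) stop("non-positive data range")
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  ux <- .gauss_filter2(reference, sigma)
  uy <- .gauss_filter2(test, sigma)
  uxx <- .gauss_filter2(reference^2, sigma)
  uyy <- .gauss_filter2(test^2, sigma)
  uxy <- .gauss_filter2(reference * test, sigma)
  vx <- uxx - ux^2
  vy <- uyy - uy^2
  cxy <- uxy - ux * uy
  s <- ((2 * ux * uy + C1) * (2 * cxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  ny <- nrow(s); nx <- ncol(s)
  if (ny > 2 * r && nx > 2 * r) {
    s <- s[(r + 1):(ny - r), (r + 1):(nx - r)]
  }
  mean(s)
}

#' Normalised root-mean-square error
#'
#' @param reference,test arrays of identical shape (complex allowed;
#'   magnitudes are compared elementwise as complex differences).
#' @return `||test - reference|| / ||reference||`.
#' @export
nrmse <- function(reference, test) {
  stopifnot(all(dim(reference) == dim(test)))
  sqrt(sum(Mod(test - reference)^2) / sum(Mod(reference)^2))
}

#' Compare sampling patterns by reconstruction quality
#'
#' For each slice count, simulates a static textured phantom, reconstructs a
#' clean fully sampled CG-SENSE reference (eddy-free ASOS at the Nyquist
#' spoke count), then for each pattern simulates an accelerated acquisition
#' (optionally with the eddy-current model), runs the compressed-sensing
#' reconstruction and reports the SSIM of the central frame's central slice
#' against the reference, plus the NRMSE. Deterministic given the seeds.
#'
#' @param patterns character vector of pattern names.
#' @param n_slices_list integer vector of prescribed slice counts.
#' @param matrix in-plane grid size (64 keeps runtimes desk-scale).
#' @param n_coils simulated receive channels.
#' @param eddy_coupling eddy model strength passed to [simulate_kspace()].
#' @param n_frames accelerated frames to reconstruct.
#' @param config a [recon_config()].
#' @param seed base seed (phantom texture, coils).
#' @return data frame with columns `pattern`, `n_slices`, `ssim`, `nrmse`.
#' @export
compare_patterns <- function(patterns = c("ASOS", "RSOS_PSI1", "RSOS_PSI9"),
                             n_slices_list = 7, matrix = 64, n_coils = 4,
                             eddy_coupling = 0, n_frames = 5,
                             config = recon_config(iterations = 15),
                             seed = 1) {
  out <- NULL
  for (ns in n_slices_list) {
    params <- sequence_params(matrix = matrix, n_readout = 2 * matrix,
                              n_slices = ns)
    nkz <- n_kz(params)
    scene <- static_phantom(matrix, nkz, texture_seed = seed)
    maps <- coil_sensitivities(n_coils, c(nkz, matrix, matrix), seed = seed)
    ref_data <- acquire_fully_sampled(scene, "ASOS", params, maps)
    est_maps <- estimate_sensitivities(ref_data)
    ref_img <- reference_recon(ref_data, est_maps)
    zc <- floor(nkz / 2) + 1L
    ref_slice <- Mod(array(ref_img$frames[1, , , ], dim(ref_img$frames)[2:4])[zc, , ])
    for (p in patterns) {
      spokes <- n_frames * config$spokes_per_slice_per_frame
      sched <- build_schedule(trajectory_config(p, spokes, params))
      kd <- simulate_kspace(scene, sched, maps, eddy_coupling = eddy_coupling,
                            seed = seed)
      binning <- bin_frames(sched, config$spokes_per_slice_per_frame)
      cs <- cs_recon(kd, binning, est_maps, config)
      fc <- ceiling(binning$n_frames / 2)
      cs_slice <- Mod(array(cs$frames[fc, , , ], dim(cs$frames)[2:4])[zc, , ])
      out <- rbind(out, data.frame(
        pattern = p, n_slices = ns,
        ssim = ssim(ref_slice, cs_slice, data_range = max(ref_slice)),
        nrmse = nrmse(ref_slice, cs_slice)))
    }
  }
  out
}
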