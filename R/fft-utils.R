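# Centered-FFT helpers shared by the NUFFT, the PSF module and the phantom
# forward model. All transforms are unscaled (R's `fft` convention), so
# forward (negative exponent) and inverse (positive exponent) are exact
# adjoints of each other.

# index permutation putting DC (index 1) at centre floor(n/2) (0-based)
.fftshift_idx <- function(n) ((seq_len(n) - 1L + as.integer(ceiling(n / 2))) %% n) + 1L

.ifftshift_idx <- function(n) ((seq_len(n) - 1L + as.integer(floor(n / 2))) %% n) + 1L

.fftshift2 <- function(m) m[.fftshift_idx(nrow(m)), .fftshift_idx(ncol(m)), drop = FALSE]

.ifftshift2 <- function(m) m[.ifftshift_idx(nrow(m)), .ifftshift_idx(ncol(m)), drop = FALSE]

# centered 2D DFT of a matrix indexed [y, x] with both axes centred:
# X(k) = sum_x x(r) exp(-2i pi k.r / N), k and r centred integers
.cfft2 <- function(m, inverse = FALSE) {
  .fftshift2(fft(.ifftshift2(m), inverse = inverse))
}

# centered DFT along the first dimension of an array (used for the Cartesian
# kz direction of the stack-of-stars); unscaled in both directions.
.cfft_dim1 <- function(arr, inverse = FALSE) {
  d <- dim(arr)
  n <- d[1]
  m <- matrix(arr, nrow = n)
  m <- m[.ifftshift_idx(n), , drop = FALSE]
  m <- mvfft(m, inverse = inverse)
  m <- m[.fftshift_idx(n), , drop = FALSE]
  array(m, dim = d)
}

# 1D Gaussian kernel, truncated at `radius` sd-multiples (odd length)
.gauss_kernel <- function(sigma, radius = 4) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(radius * sigma)))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

# separable Gaussian filtering along one array dimension with symmetric
# (reflected) edge handling
.gauss_filter_dim <- function(arr, dim_index, sigma) {
  if (sigma <= 0) return(arr)
  d <- dim(arr)
  if (is.null(d)) d <- length(arr)
  k <- .gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  n <- d[dim_index]
  if (r == 0 || n == 1) return(arr)
  perm <- c(dim_index, seq_along(d)[-dim_index])
  a <- aperm(array(arr, dim = d), perm)
  dims_p <- dim(a)
  m <- matrix(a, nrow = n)
  pad_top <- m[pmin(r:1, n), , drop = FALSE]
  pad_bot <- m[pmax(n - (1:r) + 1L, 1L), , drop = FALSE]
  mp <- rbind(pad_top, m, pad_bot)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * mp[(j - 1L) + seq_len(n), , drop = FALSE]
  }
  a <- array(out, dim = dims_p)
  aperm(a, order(perm))
}

# Gaussian smoothing of a 3D (z,y,x) volume with per-axis sigmas in voxels
.gauss_filter3 <- function(vol, sigma_vox) {
  out <- vol
  for (i in 1:3) out <- .gauss_filter_dim(out, i, sigma_vox[i])
  out
}
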