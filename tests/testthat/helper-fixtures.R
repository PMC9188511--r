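# Shared fixtures and independent oracles. Everything is generated in code;
# heavy intermediates are cached per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

tiny_params <- function() {
  sequence_params(matrix = 32, n_readout = 64, n_slices = 3,
                  oversampling_factor = 1)
}

tiny_scene <- function() cached("tiny_scene", static_phantom(32, 3, 1))

tiny_maps <- function() {
  cached("tiny_maps", coil_sensitivities(3, c(3, 32, 32), seed = 2))
}

# protocol-scale fixture (matrix 64, 9 kz, 4 coils, fully sampled ASOS)
acc64 <- function() {
  cached("acc64", {
    p <- sequence_params(matrix = 64, n_readout = 128, n_slices = 7)
    nkz <- n_kz(p)
    sc <- static_phantom(64, nkz, texture_seed = 1)
    maps <- coil_sensitivities(4, c(nkz, 64, 64), seed = 2)
    kd <- acquire_fully_sampled(sc, "ASOS", p, maps)
    list(p = p, nkz = nkz, sc = sc, maps = maps, kd = kd,
         ref = reference_recon(kd, maps))
  })
}

# empirical coil covariance of flattened samples (nsamp x ncoil), C_ij =
# E[n_i conj(n_j)]
empirical_cov <- function(x) (t(x) %*% Conj(x)) / nrow(x)

# ---- independent direct-DFT oracle (plain R sums, no gridding) ----

# forward: s(k) = sum over voxels of vol * exp(-2i pi (kx x + ky y)/N
#                                              - 2i pi kz z / n_kz)
# with centred voxel coordinates; evaluated per sample
direct_sos_forward <- function(vol, coords, n_img) {
  d <- dim(vol)
  nkz <- d[1]
  zc <- (seq_len(nkz) - 1) - floor(nkz / 2)
  yc <- (seq_len(n_img) - 1) - n_img / 2
  xc <- yc
  nev <- dim(coords)[1]
  nro <- dim(coords)[2]
  out <- matrix(0i, nev, nro)
  zphase_cache <- list()
  for (e in seq_len(nev)) {
    for (j in seq_len(nro)) {
      kx <- coords[e, j, 1]; ky <- coords[e, j, 2]; kz <- coords[e, j, 3]
      px <- exp(-2i * pi * kx * xc / n_img)
      py <- exp(-2i * pi * ky * yc / n_img)
      pz <- exp(-2i * pi * kz * zc / nkz)
      acc <- 0i
      for (z in seq_len(nkz)) {
        acc <- acc + pz[z] * sum(vol[z, , ] * outer(py, px))
      }
      out[e, j] <- acc
    }
  }
  out
}

# adjoint: x(r) = sum over samples of s * conj(phase)
direct_sos_adjoint <- function(samples, coords, n_img, nkz, weights = NULL) {
  zc <- (seq_len(nkz) - 1) - floor(nkz / 2)
  yc <- (seq_len(n_img) - 1) - n_img / 2
  xc <- yc
  out <- array(0i, dim = c(nkz, n_img, n_img))
  nev <- dim(coords)[1]
  nro <- dim(coords)[2]
  for (e in seq_len(nev)) {
    for (j in seq_len(nro)) {
      kx <- coords[e, j, 1]; ky <- coords[e, j, 2]; kz <- coords[e, j, 3]
      s <- samples[e, j]
      if (!is.null(weights)) s <- s * weights[j]
      px <- exp(2i * pi * kx * xc / n_img)
      py <- exp(2i * pi * ky * yc / n_img)
      pz <- exp(2i * pi * kz * zc / nkz)
      for (z in seq_len(nkz)) {
        out[z, , ] <- out[z, , ] + s * pz[z] * outer(py, px)
      }
    }
  }
  out
}

rel_err <- function(a, b) sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))

# ---- independent naive SSIM (explicit loops over local windows) ----

naive_ssim <- function(x, y, sigma = 1.5, data_range = max(x),
                       K1 = 0.01, K2 = 0.03) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  w2 <- outer(k, k)
  n <- nrow(x); m <- ncol(x)
  pad <- function(im) {
    im2 <- rbind(im[r:1, , drop = FALSE], im, im[n:(n - r + 1), , drop = FALSE])
    cbind(im2[, r:1, drop = FALSE], im2, im2[, m:(m - r + 1), drop = FALSE])
  }
  xp <- pad(x); yp <- pad(y)
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  vals <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      wx <- xp[i:(i + 2 * r), j:(j + 2 * r)]
      wy <- yp[i:(i + 2 * r), j:(j + 2 * r)]
      ux <- sum(w2 * wx); uy <- sum(w2 * wy)
      vx <- sum(w2 * wx^2) - ux^2
      vy <- sum(w2 * wy^2) - uy^2
      cxy <- sum(w2 * wx * wy) - ux * uy
      vals[i, j] <- ((2 * ux * uy + C1) * (2 * cxy + C2)) /
        ((ux^2 + uy^2 + C1) * (vx + vy + C2))
    }
  }
  if (n > 2 * r && m > 2 * r) vals <- vals[(r + 1):(n - r), (r + 1):(m - r)]
  mean(vals)
}

# ---- independent 1D TV prox oracle: projected gradient on the dual ----

tv_prox_dual_oracle <- function(y, lam, iters = 50000) {
  n <- length(y)
  if (n < 2) return(y)
  u <- numeric(n - 1)
  Dt <- function(u) c(-u[1], if (n > 2) -diff(u) else NULL, u[n - 1])
  for (i in seq_len(iters)) {
    u <- pmin(pmax(u - 0.25 * diff(Dt(u) - y), -lam), lam)
  }
  y - Dt(u)
}
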