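# Internal separable-convolution machinery shared by the PSF renderer and
# the a-trous wavelet denoiser.  Everything works on plain arrays/matrices
# and is fully vectorised: a 1D kernel is applied as a sum of shifted
# copies, which is fast in R for the short kernels used here.

# Shift the rows of a matrix by `t` (positive = down), padding according to
# `boundary`: "zero" pads with 0, "reflect" mirrors (symmetric half-sample).
shift_rows <- function(m, t, boundary = "zero") {
  n <- nrow(m)
  if (t == 0) return(m)
  idx <- seq_len(n) - t
  if (boundary == "reflect") {
    idx <- ifelse(idx < 1L, 1L - idx, idx)
    idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
    # repeated reflection for shifts beyond one mirror (large dilations)
    while (any(idx < 1L | idx > n)) {
      idx <- ifelse(idx < 1L, 1L - idx, idx)
      idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
    }
    m[idx, , drop = FALSE]
  } else {
    out <- matrix(0, n, ncol(m))
    keep <- idx >= 1L & idx <= n
    out[keep, ] <- m[idx[keep], , drop = FALSE]
    out
  }
}

# 1D convolution along the rows of a matrix with kernel `k` centred at
# `offsets` (integer shifts, same length as k).
conv_rows <- function(m, k, offsets, boundary = "zero") {
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) {
    out <- out + k[i] * shift_rows(m, offsets[i], boundary)
  }
  out
}

# Separable convolution of a 3D array along one dimension (1=y, 2=x, 3=z).
conv_dim3 <- function(a, k, offsets, dim, boundary = "zero") {
  d <- dim(a)
  if (dim == 1L) {
    out <- conv_rows(matrix(a, d[1], d[2] * d[3]), k, offsets, boundary)
  } else if (dim == 2L) {
    ap <- aperm(a, c(2L, 1L, 3L))
    out <- conv_rows(matrix(ap, d[2], d[1] * d[3]), k, offsets, boundary)
    return(aperm(array(out, c(d[2], d[1], d[3])), c(2L, 1L, 3L)))
  } else {
    ap <- aperm(a, c(3L, 1L, 2L))
    out <- conv_rows(matrix(ap, d[3], d[1] * d[2]), k, offsets, boundary)
    return(aperm(array(out, c(d[3], d[1], d[2])), c(2L, 3L, 1L)))
  }
  array(out, d)
}

gaussian_kernel <- function(sigma_px) {
  if (sigma_px <= 0) return(list(k = 1, offsets = 0L))
  half <- max(1L, ceiling(4 * sigma_px))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma_px^2))
  list(k = k / sum(k), offsets = as.integer(x))
}

# Anisotropic Gaussian blur of a (ny, nx, nz) array; sigmas in pixels/planes.
gaussian_blur3 <- function(a, sigma_y, sigma_x, sigma_z, boundary = "zero") {
  for (spec in list(list(sigma_y, 1L), list(sigma_x, 2L), list(sigma_z, 3L))) {
    if (spec[[1]] > 0 && dim(a)[spec[[2]]] > 1L) {
      kk <- gaussian_kernel(spec[[1]])
      a <- conv_dim3(a, kk$k, kk$offsets, spec[[2]], boundary)
    }
  }
  a
}

# 2D Gaussian blur of a matrix (used on single planes).
gaussian_blur2 <- function(m, sigma_px, boundary = "reflect") {
  kk <- gaussian_kernel(sigma_px)
  m <- conv_rows(m, kk$k, kk$offsets, boundary)
  t(conv_rows(t(m), kk$k, kk$offsets, boundary))
}
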