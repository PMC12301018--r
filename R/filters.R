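# Separable 3D filtering primitives used by preprocessing and the synthetic
# generator. Arrays are (z, y, x); no NA values are expected in image data.

# Shift an array by `s` voxels along `axis`; vacated positions take `pad`,
# or replicate the edge when pad = "clamp".
shift_axis <- function(a, s, axis, pad = 0) {
  if (s == 0) return(a)
  d <- dim(a)
  n <- d[axis]
  idx <- seq_len(n) - s
  if (identical(pad, "clamp")) {
    idx <- pmin(pmax(idx, 1L), n)
  } else {
    idx[idx < 1L | idx > n] <- NA_integer_
  }
  args <- rep(list(quote(expr = )), length(d))
  args[[axis]] <- idx
  out <- do.call(`[`, c(list(a), args, list(drop = FALSE)))
  if (!identical(pad, "clamp") && anyNA(out)) out[is.na(out)] <- pad
  dim(out) <- d
  out
}

# 1D convolution of a vector with a centered kernel, zero padding.
conv_vec <- function(v, kernel) {
  r <- (length(kernel) - 1L) / 2L
  out <- numeric(length(v))
  for (i in seq_along(kernel)) {
    s <- i - 1L - r
    shifted <- if (s == 0) v else {
      idx <- seq_along(v) - s
      w <- ifelse(idx < 1L | idx > length(v), 0, v[pmin(pmax(idx, 1L), length(v))])
      w
    }
    out <- out + kernel[i] * shifted
  }
  out
}

# Convolve along one axis with a centered kernel. With renormalize = TRUE the
# result is divided by the convolution of an all-ones field, so constant
# inputs stay constant up to the boundary (normalized correlation).
conv_axis <- function(a, kernel, axis, renormalize = TRUE) {
  r <- (length(kernel) - 1L) / 2L
  out <- array(0, dim(a))
  for (i in seq_along(kernel)) {
    s <- i - 1L - r
    out <- out + kernel[i] * shift_axis(a, s, axis, pad = 0)
  }
  if (renormalize) {
    w <- conv_vec(rep(1, dim(a)[axis]), kernel)
    out <- sweep(out, axis, w, "/")
  }
  out
}

gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur; sigma_vox is per-axis (z, y, x) in voxels.
gauss_blur <- function(a, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0) a <- conv_axis(a, gaussian_kernel(sigma_vox[ax]), ax)
  }
  a
}

# Gaussian-weighted local linear smoother along one axis (Savitzky-Golay,
# order 1). Unlike a plain weighted mean it reproduces linear trends exactly
# at the volume edges, which matters when the quantity being estimated is a
# slowly varying illumination gain.
smooth_local_linear_axis <- function(a, sigma, axis) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  offs <- (-r):r
  k <- exp(-offs^2 / (2 * sigma^2))
  n <- dim(a)[axis]
  m0 <- m1 <- m2 <- numeric(n)
  pos <- seq_len(n)
  for (t in seq_along(offs)) {
    s <- offs[t]
    valid <- (pos + s) >= 1 & (pos + s) <= n
    m0 <- m0 + k[t] * valid
    m1 <- m1 + k[t] * s * valid
    m2 <- m2 + k[t] * s^2 * valid
  }
  s0 <- array(0, dim(a)); s1 <- array(0, dim(a))
  for (t in seq_along(offs)) {
    s <- offs[t]
    sh <- shift_axis(a, -s, axis, pad = 0)   # sh[i] = a[i + s]
    s0 <- s0 + k[t] * sh
    s1 <- s1 + k[t] * s * sh
  }
  det <- m0 * m2 - m1^2
  num <- sweep(s0, axis, m2, `*`) - sweep(s1, axis, m1, `*`)
  sweep(num, axis, pmax(det, .Machine$double.xmin), `/`)
}

# Separable local-linear Gaussian smoothing (per-axis sigma in voxels).
smooth_local_linear <- function(a, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  for (ax in 1:3) a <- smooth_local_linear_axis(a, sigma_vox[ax], ax)
  a
}

# Separable running min/max with a box of half-width r_vox per axis
# (edge-replicated), the building blocks of grayscale erosion/dilation.
box_extreme <- function(a, r_vox, fun) {
  r_vox <- rep_len(as.integer(r_vox), 3L)
  for (ax in 1:3) {
    if (r_vox[ax] <= 0) next
    acc <- a
    for (s in c(-(r_vox[ax]:1), 1:r_vox[ax])) {
      acc <- fun(acc, shift_axis(a, s, ax, pad = "clamp"))
    }
    a <- acc
  }
  a
}

box_min <- function(a, r_vox) box_extreme(a, r_vox, pmin)
box_max <- function(a, r_vox) box_extreme(a, r_vox, pmax)

# Median filter over an axis-aligned ellipsoid neighborhood (radius in voxels
# per axis). Brute force via neighborhood gather; meant for modest volumes.
median_filter <- function(a, r_vox) {
  r_vox <- rep_len(as.integer(r_vox), 3L)
  offs <- expand.grid(dz = -r_vox[1]:r_vox[1],
                      dy = -r_vox[2]:r_vox[2],
                      dx = -r_vox[3]:r_vox[3])
  rr <- pmax(r_vox, 1L)
  keep <- (offs$dz / rr[1])^2 + (offs$dy / rr[2])^2 + (offs$dx / rr[3])^2 <= 1 + 1e-9
  offs <- offs[keep, , drop = FALSE]
  cols <- lapply(seq_len(nrow(offs)), function(i) {
    b <- shift_axis(a, offs$dz[i], 1L, pad = "clamp")
    b <- shift_axis(b, offs$dy[i], 2L, pad = "clamp")
    b <- shift_axis(b, offs$dx[i], 3L, pad = "clamp")
    as.vector(b)
  })
  m <- do.call(cbind, cols)
  out <- apply(m, 1L, stats::median)
  array(out, dim(a))
}

# Physical radius (um) to per-axis voxel radius, rounded half-up, >= 0.
um_to_vox <- function(r_um, voxel_size) {
  as.integer(floor(r_um / voxel_size + 0.5))
}
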