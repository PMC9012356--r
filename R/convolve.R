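# Separable 3D convolutions used by the smoothing and morphology steps.
# Kernels are applied axis by axis via dense band matrices; boundaries are
# zero-padded, which is why callers normalise by a convolved mask.

conv_axis <- function(arr, kernel, axis) {
  r <- (length(kernel) - 1L) / 2L
  dm <- dim(arr)
  n <- dm[axis]
  # band matrix K[i, j] = kernel weight for source j contributing to target i
  K <- matrix(0, n, n)
  for (off in -r:r) {
    idx <- seq_len(n)
    src <- idx + off
    ok <- src >= 1L & src <= n
    K[cbind(idx[ok], src[ok])] <- kernel[off + r + 1L]
  }
  perm <- switch(axis, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
                 `3` = c(3L, 1L, 2L))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = n)
  out <- K %*% m
  out <- array(out, dim = dm[perm])
  aperm(out, order(perm))
}

gaussian_kernel_1d <- function(sigma_vox, truncate = 3) {
  r <- ceiling(truncate * sigma_vox)
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Separable Gaussian; sigma_vox is per-axis in voxel units (0 = skip axis)
gaussian_blur <- function(arr, sigma_vox, truncate = 3) {
  out <- arr
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0)
      out <- conv_axis(out, gaussian_kernel_1d(sigma_vox[ax], truncate), ax)
  }
  out
}

# Neighbourhood count over a (2r+1)^3 box, for binary morphology
box_count <- function(mask, r = 1L) {
  k <- rep(1, 2L * r + 1L)
  out <- array(as.numeric(mask), dim(mask))
  for (ax in 1:3) out <- conv_axis(out, k, ax)
  out
}

dilate3 <- function(mask, r = 1L) box_count(mask, r) > 0.5

erode3 <- function(mask, r = 1L) {
  box_count(mask, r) > (2L * r + 1L)^3 - 0.5
}

close3 <- function(mask, r = 1L) {
  # zero-padded boundary makes erosion of the dilation conservative at the
  # grid edge, which is the behaviour we want for brain masks
  erode3(dilate3(mask, r), r)
}
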