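#' Phantom generation parameters
#'
#' Describes one synthetic multi-contrast head: a stylised ellipsoidal brain
#' (CSF shell, grey-matter ribbon, white-matter core) with a
#' brainstem/cerebellum block containing the two middle cerebellar peduncle
#' (MCP) regions. Inside the block the T2w intensity is back-solved from the
#' T1w intensity and the global scaling factor so that the noiseless
#' sT1w/T2w pipeline output equals `mcp_target_ratio` exactly.
#'
#' @param grid_shape integer length-3 voxel counts (default 64^3).
#' @param voxel_size_mm numeric length-3 spacing in mm (default 2 mm
#'   isotropic).
#' @param tissue_means_t1w,tissue_means_t2w named intensity means for
#'   `csf`, `gm`, `wm` (arbitrary units, strictly positive). T1w defaults are
#'   CSF-dark/WM-bright; T2w the reverse.
#' @param mcp_target_ratio intended post-pipeline sT1w/T2w value in the MCP,
#'   in (-1, 1). The published group means (0.07 MSA-C, 0.17 SCA3, 0.18
#'   SCA6, 0.19 controls) are the values [run_phantom_study()] draws around.
#' @param bias_amplitude peak fractional deviation of the multiplicative
#'   intensity-inhomogeneity field inside the brain, in `[0, 1)`.
#' @param noise_sigma additive noise SD (intensity units), >= 0.
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param rigid_offset optional `rigid_transform()` applied to the T2w
#'   sampling grid (emulates separately acquired 2D T2w).
#' @param t2_slice_mm optional through-plane (z) slice thickness for the T2w
#'   image; when larger than the z voxel size the ideal T2w is boxcar-averaged
#'   over that thickness before sampling (anisotropic-acquisition mode).
#' @param seed optional RNG seed; identical specs and seeds give bit-identical
#'   phantoms.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         voxel_size_mm = c(2, 2, 2),
                         tissue_means_t1w = c(csf = 60, gm = 100, wm = 150),
                         tissue_means_t2w = c(csf = 220, gm = 110, wm = 80),
                         mcp_target_ratio = 0.19,
                         bias_amplitude = 0.2,
                         noise_sigma = 5,
                         noise_model = c("gaussian", "rician"),
                         rigid_offset = NULL,
                         t2_slice_mm = NULL,
                         seed = NULL) {
  noise_model <- match.arg(noise_model)
  for (m in list(tissue_means_t1w, tissue_means_t2w)) {
    if (!all(c("csf", "gm", "wm") %in% names(m)) || any(m <= 0))
      stop("tissue means must be named csf/gm/wm and strictly positive")
  }
  if (bias_amplitude < 0 || bias_amplitude >= 1)
    stop("`bias_amplitude` must lie in [0, 1)")
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  if (abs(mcp_target_ratio) >= 1) stop("|mcp_target_ratio| must be < 1")
  if (!is.null(rigid_offset) && !inherits(rigid_offset, "rigid_transform"))
    stop("`rigid_offset` must be a rigid_transform()")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 tissue_means_t1w = tissue_means_t1w,
                 tissue_means_t2w = tissue_means_t2w,
                 mcp_target_ratio = mcp_target_ratio,
                 bias_amplitude = bias_amplitude,
                 noise_sigma = noise_sigma,
                 noise_model = noise_model,
                 rigid_offset = rigid_offset,
                 t2_slice_mm = t2_slice_mm,
                 seed = seed),
            class = "phantom_spec")
}

# Geometry of the stylised head, scaled to the grid's field of view so that
# normalised quantities (e.g. MCP volume / ICV) are grid-independent. All
# lengths in world mm; the world origin sits at the grid centre.
phantom_geometry <- function(grid_shape, voxel_size_mm) {
  h <- grid_shape * voxel_size_mm / 2        # per-axis half field of view
  list(
    brain_radii = c(0.906, 0.969, 0.875) * h,
    csf_inner = 0.88,                        # normalised radii of the shells
    gm_inner = 0.75,
    block_center = c(0, -0.15625, -0.25) * h,
    block_half = c(0.59375, 0.265625, 0.265625) * h,
    roi = list(
      left  = list(center = c(-0.3125, -0.171875, -0.25) * h,
                   radii = c(0.1334, 0.1084, 0.1028) * h),
      right = list(center = c(0.3125, -0.171875, -0.25) * h,
                   radii = c(0.1334, 0.1084, 0.1028) * h))
  )
}

#' Label codes used by truth labels and segmentation output
#' @format named integer vector (background 0, csf 1, gm 2, wm 3)
#' @export
TISSUE_LABELS <- c(background = 0L, csf = 1L, gm = 2L, wm = 3L)

#' Generate one synthetic subject phantom
#'
#' Produces paired T1w/T2w volumes plus ground truth: tissue labels, binary
#' MCP masks, the multiplicative bias field, the T2w rigid offset (if any) and
#' the constructed MCP ratio. Construction order: piecewise-constant tissue
#' intensities, MCP/brainstem T2w calibration, multiplicative bias field
#' (shared by both contrasts), optional T2w thick-slice averaging and rigid
#' resampling, additive noise last.
#'
#' The calibration back-solves, with `s` the noiseless scaling factor from
#' grey-matter means and `r*` the target ratio,
#' `T2w = T1w * (1 - r*) / ((1 + r*) * s)` throughout the
#' brainstem/cerebellum block, so the noiseless, bias-free pipeline reproduces
#' `r*` exactly (the constant-ratio block extends beyond the smoothing
#' kernel's support around the MCP ROIs).
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `subject_phantom`; see fields in the source.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec()")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  dm <- spec$grid_shape
  vox <- spec$voxel_size_mm
  geom <- phantom_geometry(dm, vox)
  affine <- centered_affine(dm, vox)
  ref <- volume(array(0, dm), vox, affine)
  xs <- axis_world(ref, 1); ys <- axis_world(ref, 2); zs <- axis_world(ref, 3)

  u2 <- ellipsoid_q2(dm, xs, ys, zs, c(0, 0, 0), geom$brain_radii)
  brain <- u2 <= 1
  labels <- array(TISSUE_LABELS[["background"]], dm)
  labels[brain] <- TISSUE_LABELS[["csf"]]
  labels[u2 <= geom$csf_inner^2] <- TISSUE_LABELS[["gm"]]
  labels[u2 <= geom$gm_inner^2] <- TISSUE_LABELS[["wm"]]

  inbox <- outer_box(dm, xs, ys, zs, geom$block_center, geom$block_half) & brain
  labels[inbox] <- TISSUE_LABELS[["wm"]]

  atlas <- make_atlas(dm, vox, geom$roi)
  mcp_left <- atlas_mask(atlas, "left")
  mcp_right <- atlas_mask(atlas, "right")

  m1 <- spec$tissue_means_t1w; m2 <- spec$tissue_means_t2w
  lut1 <- c(0, m1[["csf"]], m1[["gm"]], m1[["wm"]])
  lut2 <- c(0, m2[["csf"]], m2[["gm"]], m2[["wm"]])
  t1 <- array(lut1[labels + 1L], dm)
  t2 <- array(lut2[labels + 1L], dm)

  s_cal <- m1[["gm"]] / m2[["gm"]]
  r <- spec$mcp_target_ratio
  t2[inbox] <- t1[inbox] * (1 - r) / ((1 + r) * s_cal)

  field <- array(1, dm)
  if (spec$bias_amplitude > 0) {
    P <- poly_basis(dm, xs, ys, zs, order = 2L)
    logf <- as.vector(P %*% stats::rnorm(ncol(P)))
    logf <- logf - mean(logf[brain])
    logf <- logf * (log1p(spec$bias_amplitude) / max(abs(logf[brain])))
    field <- array(exp(logf), dm)
    field <- field / mean(field[brain])
  }
  t1 <- t1 * field
  t2 <- t2 * field

  t2_vol <- volume(t2, vox, affine)
  if (!is.null(spec$t2_slice_mm) && spec$t2_slice_mm > vox[3]) {
    w <- max(1L, round(spec$t2_slice_mm / vox[3]))
    if (w %% 2L == 0L) w <- w + 1L
    t2_vol$values <- conv_axis(t2_vol$values, rep(1 / w, w), 3L)
  }
  if (!is.null(spec$rigid_offset)) {
    t2_vol <- resample_rigid(t2_vol, ref, spec$rigid_offset)$volume
  }

  if (spec$noise_sigma > 0) {
    n <- prod(dm)
    if (spec$noise_model == "gaussian") {
      t1 <- t1 + stats::rnorm(n, 0, spec$noise_sigma)
      t2v <- t2_vol$values + stats::rnorm(n, 0, spec$noise_sigma)
    } else {
      t1 <- sqrt((t1 + stats::rnorm(n, 0, spec$noise_sigma))^2 +
                   stats::rnorm(n, 0, spec$noise_sigma)^2)
      t2v <- sqrt((t2_vol$values + stats::rnorm(n, 0, spec$noise_sigma))^2 +
                    stats::rnorm(n, 0, spec$noise_sigma)^2)
    }
    t2_vol$values <- array(t2v, dm)
    t1 <- array(t1, dm)
  }

  structure(list(t1w = volume(t1, vox, affine),
                 t2w = t2_vol,
                 truth_labels = labels,
                 truth_mcp_left = mcp_left,
                 truth_mcp_right = mcp_right,
                 truth_bias_field = volume(field, vox, affine),
                 truth_transform = spec$rigid_offset,
                 truth_mcp_ratio = r,
                 atlas = atlas,
                 spec = spec),
            class = "subject_phantom")
}

outer_box <- function(dm, xs, ys, zs, center, half) {
  bx <- abs(xs - center[1]) <= half[1]
  by <- abs(ys - center[2]) <= half[2]
  bz <- abs(zs - center[3]) <= half[3]
  array(rep(bx, times = dm[2] * dm[3]) &
          rep(rep(by, each = dm[1]), times = dm[3]) &
          rep(bz, each = dm[1] * dm[2]), dm)
}

# polynomial basis (degree <= order, no intercept) on coords normalised to
# [-1, 1] per axis; rows follow R array order
poly_basis <- function(dm, xs, ys, zs, order = 2L) {
  nx <- xs / max(abs(xs)); ny <- ys / max(abs(ys)); nz <- zs / max(abs(zs))
  X <- rep(nx, times = dm[2] * dm[3])
  Y <- rep(rep(ny, each = dm[1]), times = dm[3])
  Z <- rep(nz, each = dm[1] * dm[2])
  cols <- list(X, Y, Z)
  if (order >= 2L)
    cols <- c(cols, list(X * X, Y * Y, Z * Z, X * Y, X * Z, Y * Z))
  if (order >= 3L) {
    cols <- c(cols, list(X^3, Y^3, Z^3, X * X * Y, X * X * Z, Y * Y * X,
                         Y * Y * Z, Z * Z * X, Z * Z * Y, X * Y * Z))
  }
  do.call(cbind, cols)
}

#' @export
print.subject_phantom <- function(x, ...) {
  cat(sprintf(
    "<subject_phantom> %s voxels; target MCP ratio %.4f; noise sd %.3g; bias %.3g\n",
    paste(dim(x$t1w$values), collapse = " x "), x$truth_mcp_ratio,
    x$spec$noise_sigma, x$spec$bias_amplitude))
  invisible(x)
}
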