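#' Synthetic probabilistic MCP atlas
#'
#' Builds a two-channel (left/right) probabilistic atlas of the middle
#' cerebellar peduncles on a voxel grid. Each channel is an analytic radial
#' profile over an ellipsoidal support: with `q` the normalised ellipsoidal
#' radius (0 at the centre, 1 at the support boundary), the membership
#' probability is `p = max(0, 1 - q^4)`, so `p = 1` exactly at the ROI centre
#' and decays smoothly to 0 at the support edge. Thresholding at 0.90 (the
#' parcellation level used downstream) selects the core `q <= 0.1^(1/4)`.
#'
#' This is a synthetic stand-in for a population atlas of cerebellar white
#' matter; it shares a grid with the phantoms produced by [make_phantom()].
#'
#' @param grid_shape integer length-3 voxel counts.
#' @param voxel_size_mm numeric length-3 spacings (mm).
#' @param roi_geometry list with elements `left` and `right`, each a list with
#'   `center` (world mm) and `radii` (mm, support semi-axes). Defaults to the
#'   geometry used by the phantom generator.
#' @return an object of class `prob_atlas` with fields `left`, `right`
#'   (probability arrays), `affine`, `voxel_size`, `roi_geometry`.
#' @export
make_atlas <- function(grid_shape = c(64, 64, 64),
                       voxel_size_mm = c(2, 2, 2),
                       roi_geometry = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (is.null(roi_geometry))
    roi_geometry <- phantom_geometry(grid_shape, voxel_size_mm)$roi
  affine <- centered_affine(grid_shape, voxel_size_mm)
  ref <- volume(array(0, grid_shape), voxel_size_mm, affine)
  xs <- axis_world(ref, 1); ys <- axis_world(ref, 2); zs <- axis_world(ref, 3)
  lo <- c(min(xs), min(ys), min(zs)); hi <- c(max(xs), max(ys), max(zs))
  chan <- function(g) {
    if (any(g$center - g$radii < lo) || any(g$center + g$radii > hi))
      stop("ROI support extends beyond the atlas grid")
    q2 <- ellipsoid_q2(grid_shape, xs, ys, zs, g$center, g$radii)
    p <- 1 - q2^2          # q^4 with q2 = q^2
    p[q2 > 1] <- 0
    p
  }
  structure(list(left = chan(roi_geometry$left),
                 right = chan(roi_geometry$right),
                 affine = affine, voxel_size = as.numeric(voxel_size_mm),
                 roi_geometry = roi_geometry),
            class = "prob_atlas")
}

# squared normalised ellipsoidal radius on the full grid (outer-sum expansion)
ellipsoid_q2 <- function(dm, xs, ys, zs, center, radii) {
  qx <- ((xs - center[1]) / radii[1])^2
  qy <- ((ys - center[2]) / radii[2])^2
  qz <- ((zs - center[3]) / radii[3])^2
  array(rep(qx, times = dm[2] * dm[3]) +
          rep(rep(qy, each = dm[1]), times = dm[3]) +
          rep(qz, each = dm[1] * dm[2]), dm)
}

#' Threshold an atlas channel into a binary ROI mask
#'
#' @param atlas a [make_atlas()] result.
#' @param side `"left"` or `"right"`.
#' @param threshold inclusive probability threshold (default 0.90, the
#'   parcellation level used for the MCP).
#' @return logical 3D array.
#' @export
atlas_mask <- function(atlas, side = c("left", "right"), threshold = 0.90) {
  side <- match.arg(side)
  atlas[[side]] >= threshold
}

#' @export
print.prob_atlas <- function(x, ...) {
  cat(sprintf("<prob_atlas> %s voxels; P>=0.9 voxels: left %d, right %d\n",
              paste(dim(x$left), collapse = " x "),
              sum(x$left >= 0.9), sum(x$right >= 0.9)))
  invisible(x)
}
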