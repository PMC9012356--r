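#' Global intensity scaling factor from grey-matter medians
#'
#' The standardisation step of the sT1w/T2w ratio: `s` is the median
#' grey-matter T1w intensity divided by the median grey-matter T2w intensity.
#' White-matter medians are computed and recorded for QC but play no part in
#' `s`.
#'
#' @param t1w,t2w co-registered [volume()]s on one grid.
#' @param gm_mask logical grey-matter mask (nonempty).
#' @param wm_mask optional logical white-matter mask (QC only).
#' @return object of class `scaling_factor` with fields `s`,
#'   `gm_median_t1w`, `gm_median_t2w`, `wm_median_t1w`, `wm_median_t2w`.
#' @export
scaling_factor <- function(t1w, t2w, gm_mask, wm_mask = NULL) {
  stopifnot_volume(t1w); stopifnot_volume(t2w)
  require_same_grid(t1w, t2w)
  gm_mask <- as.logical(gm_mask)
  if (!any(gm_mask)) stop("grey-matter mask is empty")
  g1 <- stats::median(t1w$values[gm_mask])
  g2 <- stats::median(t2w$values[gm_mask])
  if (g2 <= 0) stop("grey-matter T2w median must be positive")
  w1 <- w2 <- NA_real_
  if (!is.null(wm_mask) && any(wm_mask)) {
    w1 <- stats::median(t1w$values[as.logical(wm_mask)])
    w2 <- stats::median(t2w$values[as.logical(wm_mask)])
  }
  structure(list(s = g1 / g2, gm_median_t1w = g1, gm_median_t2w = g2,
                 wm_median_t1w = w1, wm_median_t2w = w2),
            class = "scaling_factor")
}

#' @export
print.scaling_factor <- function(x, ...) {
  cat(sprintf("<scaling_factor> s = %.6g (GM medians T1w %.6g / T2w %.6g)\n",
              x$s, x$gm_median_t1w, x$gm_median_t2w))
  invisible(x)
}

#' Standardized T1w/T2w ratio map
#'
#' Scales the T2w image by `s` (`sT2 = s * T2w`) and computes
#' `(T1w - sT2) / (T1w + sT2)` voxelwise. Voxels are valid only where both
#' T1w and sT2 are strictly positive, which guarantees the map lies strictly
#' inside (-1, 1) on valid voxels; invalid voxels are flagged (NA), never
#' silently zeroed.
#'
#' @param t1w,t2w co-registered [volume()]s.
#' @param s a [scaling_factor()] or a positive number.
#' @return object of class `ratio_map`: fields `values` (3D array, NA where
#'   invalid), `valid` (logical array), `s`, plus grid metadata.
#' @export
ratio_map <- function(t1w, t2w, s) {
  stopifnot_volume(t1w); stopifnot_volume(t2w)
  require_same_grid(t1w, t2w)
  if (inherits(s, "scaling_factor")) s <- s$s
  if (!is.numeric(s) || length(s) != 1L || s <= 0)
    stop("`s` must be a positive scalar scaling factor")
  st2 <- s * t2w$values
  valid <- t1w$values > 0 & st2 > 0
  vals <- array(NA_real_, dim(t1w$values))
  vals[valid] <- (t1w$values[valid] - st2[valid]) /
    (t1w$values[valid] + st2[valid])
  structure(list(values = vals, valid = valid, s = s,
                 affine = t1w$affine, voxel_size = t1w$voxel_size),
            class = "ratio_map")
}

#' Gaussian smoothing of a ratio map
#'
#' Separable Gaussian smoothing with the kernel width given as full width at
#' half maximum in mm (`sigma = fwhm / (2 sqrt(2 ln 2))`, converted to voxels
#' per axis). Invalid voxels are excluded by mask-normalised convolution:
#' the map (zero-filled outside the validity mask) and the mask are smoothed
#' with the same kernel and their quotient is taken, so valid voxels are
#' renormalised over their valid neighbourhood only. `fwhm_mm = 0` is the
#' identity.
#'
#' @param rmap a [ratio_map()].
#' @param fwhm_mm kernel FWHM in mm (default 8, the protocol value).
#' @return a smoothed `ratio_map` (same validity mask).
#' @export
smooth_ratio_map <- function(rmap, fwhm_mm = 8) {
  if (!inherits(rmap, "ratio_map")) stop("`rmap` must be a ratio_map")
  if (fwhm_mm < 0) stop("`fwhm_mm` must be >= 0")
  if (fwhm_mm == 0) return(rmap)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / rmap$voxel_size
  v <- rmap$values
  v[!rmap$valid] <- 0
  num <- gaussian_blur(v, sigma_vox)
  den <- gaussian_blur(array(as.numeric(rmap$valid), dim(v)), sigma_vox)
  out <- array(NA_real_, dim(v))
  ok <- rmap$valid & den > 0
  out[ok] <- num[ok] / den[ok]
  rmap$values <- out
  rmap$valid <- ok
  rmap
}

#' MCP ratio value from an atlas-parcellated ratio map
#'
#' Thresholds the probabilistic atlas at `threshold` (inclusive) on each side,
#' takes the median smoothed ratio over valid ROI voxels per side, and
#' averages the left and right medians: the subject's MCP sT1w/T2w ratio.
#'
#' @param rmap a [ratio_map()] on the atlas grid.
#' @param atlas a [make_atlas()] result.
#' @param threshold inclusive probability threshold (default 0.90).
#' @return object of class `mcp_measurement` with `left_median`,
#'   `right_median`, `mcp_value`, `n_left`, `n_right`.
#' @export
mcp_value <- function(rmap, atlas, threshold = 0.90) {
  if (!inherits(rmap, "ratio_map")) stop("`rmap` must be a ratio_map")
  if (!all(dim(rmap$values) == dim(atlas$left)))
    stop("atlas is not on the ratio-map grid")
  side_median <- function(side) {
    roi <- atlas_mask(atlas, side, threshold) & rmap$valid
    if (!any(roi)) stop(sprintf("empty thresholded %s ROI", side))
    c(stats::median(rmap$values[roi]), sum(roi))
  }
  l <- side_median("left"); r <- side_median("right")
  structure(list(left_median = l[1], right_median = r[1],
                 mcp_value = (l[1] + r[1]) / 2,
                 n_left = l[2], n_right = r[2], threshold = threshold),
            class = "mcp_measurement")
}

#' ICV-normalized MCP volume
#'
#' Counts atlas voxels at or above the probability threshold per side,
#' multiplies by the voxel volume, averages left and right, and divides by
#' the intracranial volume (the brain-mask volume), reported in the
#' `m x 10^-3` convention (ratio times 1000).
#'
#' @param atlas a [make_atlas()] result, in subject space.
#' @param brain binary brain mask (array) defining the ICV, on the same grid.
#' @param voxel_size_mm numeric length-3 voxel spacing in mm.
#' @param threshold inclusive probability threshold (default 0.90).
#' @return object of class `mcp_volume` with `left_mm3`, `right_mm3`,
#'   `mcp_volume_mm3` (mean of sides), `icv_mm3`, `mcp_volume_norm`.
#' @export
mcp_volume <- function(atlas, brain, voxel_size_mm, threshold = 0.90) {
  brain <- as.logical(brain)
  if (!any(brain)) stop("brain mask is empty")
  if (!all(dim(brain) == dim(atlas$left)))
    stop("atlas and brain mask are on different grids")
  vv <- prod(voxel_size_mm)
  nl <- sum(atlas_mask(atlas, "left", threshold))
  nr <- sum(atlas_mask(atlas, "right", threshold))
  if (nl == 0 || nr == 0) stop("empty thresholded ROI")
  icv <- sum(brain) * vv
  vol <- (nl + nr) / 2 * vv
  structure(list(left_mm3 = nl * vv, right_mm3 = nr * vv,
                 mcp_volume_mm3 = vol, icv_mm3 = icv,
                 mcp_volume_norm = vol / icv * 1e3),
            class = "mcp_volume")
}

#' Measure one subject end to end
#'
#' The full per-subject computation: preprocessing (estimated or oracle),
#' scaling factor from grey-matter medians, ratio map, common-space transform
#' (identity in the phantom world; hook for a real warp), 8-mm FWHM smoothing,
#' atlas-ROI medians, and ICV-normalised MCP volume.
#'
#' @param phantom a [make_phantom()] result.
#' @param atlas optional [make_atlas()]; defaults to the phantom's own atlas.
#' @param mode preprocessing mode, `"estimated"` or `"oracle"`.
#' @param fwhm_mm smoothing kernel FWHM in mm (default 8).
#' @param threshold atlas probability threshold (default 0.90).
#' @return one-row `data.frame` with the scaling factor, GM/WM medians,
#'   left/right/mean MCP ratio values and volume measures.
#' @export
measure_subject <- function(phantom, atlas = NULL,
                            mode = c("estimated", "oracle"),
                            fwhm_mm = 8, threshold = 0.90) {
  mode <- match.arg(mode)
  if (is.null(atlas)) atlas <- phantom$atlas
  pp <- preprocess_subject(phantom, mode = mode)
  gm <- pp$labels == TISSUE_LABELS[["gm"]]
  wm <- pp$labels == TISSUE_LABELS[["wm"]]
  s <- scaling_factor(pp$t1w, pp$t2w, gm, wm)
  rm_ <- ratio_map(pp$t1w, pp$t2w, s)
  rm_ <- smooth_ratio_map(rm_, fwhm_mm)
  mv <- mcp_value(rm_, atlas, threshold)
  vol <- mcp_volume(atlas, pp$mask, phantom$t1w$voxel_size, threshold)
  data.frame(s = s$s,
             gm_median_t1w = s$gm_median_t1w, gm_median_t2w = s$gm_median_t2w,
             wm_median_t1w = s$wm_median_t1w, wm_median_t2w = s$wm_median_t2w,
             mcp_left = mv$left_median, mcp_right = mv$right_median,
             mcp_value = mv$mcp_value,
             mcp_volume_mm3 = vol$mcp_volume_mm3, icv_mm3 = vol$icv_mm3,
             mcp_volume_norm = vol$mcp_volume_norm)
}
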