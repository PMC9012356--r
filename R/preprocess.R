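#' Estimate a smooth multiplicative bias field
#'
#' Least-squares fit of a low-order 3D polynomial to log-intensity inside a
#' mask, exponentiated and normalised to in-mask mean 1. When tissue `labels`
#' are supplied the fit includes a per-tissue intercept, so piecewise-constant
#' anatomy is absorbed by the intercepts rather than leaking into the
#' polynomial (the same idea as segmentation-coupled bias models in standard
#' tools). Without labels the fit is a plain polynomial trend in the mask.
#'
#' @param vol a [volume()] with strictly positive in-mask intensities.
#' @param mask logical array on the volume grid (nonempty).
#' @param order polynomial degree (default 2).
#' @param labels optional integer label array (e.g. from
#'   [segment_tissues()] or generator truth); zero/background labels inside
#'   the mask are treated as their own class.
#' @return a [volume()] holding the estimated field (mean 1 inside `mask`).
#' @export
estimate_bias_field <- function(vol, mask, order = 2L, labels = NULL) {
  stopifnot_volume(vol)
  mask <- as.logical(mask)
  if (!any(mask)) stop("mask is empty")
  iv <- vol$values[mask]
  if (any(iv <= 0)) stop("in-mask intensities must be strictly positive")
  dm <- dim(vol$values)
  xs <- axis_world(vol, 1); ys <- axis_world(vol, 2); zs <- axis_world(vol, 3)
  P <- poly_basis(dm, xs, ys, zs, order = as.integer(order))
  Pm <- P[as.vector(mask), , drop = FALSE]
  y <- log(iv)
  if (is.null(labels)) {
    X <- cbind(1, Pm)
  } else {
    f <- factor(as.integer(labels)[as.vector(mask)])
    X <- cbind(stats::model.matrix(~ f - 1), Pm)
  }
  beta <- stats::lm.fit(X, y)$coefficients
  beta[is.na(beta)] <- 0
  npoly <- ncol(Pm)
  bpoly <- beta[(length(beta) - npoly + 1L):length(beta)]
  logf <- as.vector(P %*% bpoly)
  field <- array(exp(logf), dm)
  field <- field / mean(field[mask])
  volume(field, vol$voxel_size, vol$affine)
}

#' Correct a volume for a multiplicative bias field
#'
#' Voxelwise division by the field; when a mask is supplied the corrected
#' image is rescaled so its in-mask mean equals the input's in-mask mean
#' (the field has mean 1 in-mask, so the rescale factor is close to 1).
#'
#' @param vol a [volume()].
#' @param field a [volume()] (or array) of strictly positive field values.
#' @param mask optional logical array; enables mean preservation and the
#'   positivity check.
#' @return the corrected [volume()].
#' @export
correct_bias <- function(vol, field, mask = NULL) {
  stopifnot_volume(vol)
  f <- if (is_volume(field)) field$values else field
  if (!all(dim(f) == dim(vol$values))) stop("field grid mismatch")
  if (is.null(mask)) {
    if (any(f <= 0)) stop("bias field must be strictly positive")
    out <- vol$values / f
  } else {
    mask <- as.logical(mask)
    if (any(f[mask] <= 0)) stop("bias field must be positive inside the mask")
    out <- vol$values / f
    out <- out * (mean(vol$values[mask]) / mean(out[mask]))
  }
  volume(array(out, dim(vol$values)), vol$voxel_size, vol$affine)
}

otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) <= 0) stop("cannot threshold a constant volume")
  h <- tabulate(pmin(pmax(findInterval(
    x, seq(rng[1], rng[2], length.out = n_bins + 1L),
    rightmost.closed = TRUE), 1L), n_bins), nbins = n_bins)
  p <- h / sum(h)
  mids <- seq(rng[1], rng[2], length.out = n_bins + 1L)[-1] -
    diff(rng) / (2 * n_bins)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

largest_component <- function(mask) {
  dm <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(mask)
  lin <- array(0L, dm)
  lin[idx] <- seq_along(idx)
  edges <- integer(0)
  for (ax in 1:3) {
    step <- c(1L, dm[1], dm[1] * dm[2])[ax]
    coord <- arrayInd(idx, dm)[, ax]
    ok <- coord < dm[ax]
    nb <- idx[ok] + step
    both <- mask[nb]
    if (any(both))
      edges <- c(edges, rbind(lin[idx[ok][both]], lin[nb[both]]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  keep <- comp$membership == which.max(comp$csize)
  out <- array(FALSE, dm)
  out[idx[keep]] <- TRUE
  out
}

#' Brain extraction by thresholding and morphology
#'
#' Otsu threshold on the log-compressed T1w histogram (the compression makes
#' the air/tissue separation dominate the within-tissue splits of the
#' multimodal histogram), restriction to the largest 6-connected component,
#' then a one-voxel morphological closing. The resulting mask defines the
#' intracranial volume (ICV) used to normalise MCP volumes.
#'
#' @param t1w a [volume()].
#' @return logical 3D array (the brain mask).
#' @export
brain_mask <- function(t1w) {
  stopifnot_volume(t1w)
  if (all(t1w$values == 0)) stop("cannot skull-strip an all-zero volume")
  lv <- log1p(pmax(t1w$values, 0))
  thr <- otsu_threshold(as.vector(lv))
  m <- lv > thr
  if (!any(m)) stop("empty mask after thresholding")
  close3(largest_component(m), r = 1L)
}

#' Three-class tissue segmentation of a masked T1w image
#'
#' One-dimensional k-means on in-mask intensities with deterministic quantile
#' initialisation; classes are relabelled by ascending mean intensity so that
#' in T1w contrast CSF < GM < WM (labels 1, 2, 3; background stays 0). The
#' result depends only on the intensity order statistics, never on RNG state.
#'
#' @param t1w a [volume()].
#' @param mask logical array (nonempty) selecting brain voxels.
#' @param k number of classes (default 3).
#' @return integer label array (see [TISSUE_LABELS]).
#' @export
segment_tissues <- function(t1w, mask, k = 3L) {
  stopifnot_volume(t1w)
  mask <- as.logical(mask)
  if (!any(mask)) stop("mask is empty")
  x <- t1w$values[mask]
  init <- unname(stats::quantile(x, (2 * seq_len(k) - 1) / (2 * k)))
  if (length(unique(init)) < k || length(unique(x)) < k)
    stop("fewer distinct intensities than classes")
  km <- stats::kmeans(x, centers = matrix(init, ncol = 1), iter.max = 100L)
  ord <- order(km$centers)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- array(0L, dim(t1w$values))
  labels[mask] <- relabel[km$cluster]
  labels
}

#' Full preprocessing of one subject's image pair
#'
#' Runs the desk-scale equivalents of the external preprocessing tools:
#' bias-field correction of both contrasts, rigid co-registration of T2w onto
#' the T1w grid, skull-stripping, and tissue segmentation. With
#' `mode = "oracle"` every output is taken from the generator's ground truth
#' (and the truth bias field is divided out), which isolates downstream
#' ratio/statistics behaviour from preprocessing error.
#'
#' @param phantom a [make_phantom()] result (or a list with `t1w`, `t2w`
#'   volumes plus truth fields for oracle mode).
#' @param mode `"estimated"` or `"oracle"`.
#' @param bias_iterations estimation passes (segment, fit, correct) used in
#'   estimated mode.
#' @param register `"identity"` (default; generator grids coincide) or
#'   `"optimize"`.
#' @return list with corrected `t1w`, `t2w`, `mask`, `labels`, `transform`.
#' @export
preprocess_subject <- function(phantom, mode = c("estimated", "oracle"),
                               bias_iterations = 2L,
                               register = c("identity", "optimize")) {
  mode <- match.arg(mode)
  register <- match.arg(register)
  t1 <- phantom$t1w; t2 <- phantom$t2w
  if (mode == "oracle") {
    mask <- phantom$truth_labels > 0L
    t1 <- correct_bias(t1, phantom$truth_bias_field, mask)
    t2 <- correct_bias(t2, phantom$truth_bias_field, mask)
    reg <- register_rigid(t2, t1, mode = "identity")
    return(list(t1w = t1, t2w = reg$volume, mask = mask,
                labels = phantom$truth_labels, transform = reg$transform))
  }
  reg <- register_rigid(t2, t1, mode = register)
  t2 <- reg$volume
  mask <- brain_mask(t1)
  labels <- NULL
  # The inhomogeneity is a receiver-coil field shared by the two contrasts,
  # so one field is estimated from the T1w image (iterating the
  # segment/fit/correct cycle) and divided out of both. Correcting each
  # contrast with its own independently fitted field would let small,
  # contrast-dependent fit errors break the voxelwise cancellation of the
  # common field in the ratio map.
  for (it in seq_len(max(1L, bias_iterations))) {
    labels <- segment_tissues(t1, mask)
    m1 <- mask & t1$values > 0   # noise can push edge voxels nonpositive
    f1 <- estimate_bias_field(t1, m1, labels = labels)
    t1 <- correct_bias(t1, f1, m1)
    t2 <- correct_bias(t2, f1, mask & t2$values > 0)
  }
  labels <- segment_tissues(t1, mask)
  list(t1w = t1, t2w = t2, mask = mask, labels = labels,
       transform = reg$transform)
}
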