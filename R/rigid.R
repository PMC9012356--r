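#' Rigid (6-parameter) spatial transform
#'
#' Rotations in degrees about the world x, y, z axes (applied as
#' `Rz %*% Ry %*% Rx`) followed by a translation in mm. The rotation pivots
#' about a centre point (by default the world origin, which for package
#' volumes is the grid centre). Mapping: `y = R (x - c) + c + t`.
#'
#' @param rotation_deg numeric length-3 rotations (degrees).
#' @param translation_mm numeric length-3 translation (mm).
#' @param center rotation centre in world mm.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation_deg = c(0, 0, 0),
                            translation_mm = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  structure(list(rotation_deg = as.numeric(rotation_deg),
                 translation_mm = as.numeric(translation_mm),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot (deg) [%s], trans (mm) [%s]\n",
              paste(sprintf("%.3f", x$rotation_deg), collapse = ", "),
              paste(sprintf("%.3f", x$translation_mm), collapse = ", ")))
  invisible(x)
}

rotation_matrix <- function(rotation_deg) {
  a <- rotation_deg * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])),
              c(0, sin(a[1]), cos(a[1])))
  Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0),
              c(-sin(a[2]), 0, cos(a[2])))
  Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0),
              c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' 4x4 homogeneous matrix of a rigid transform
#' @param tf a [rigid_transform()].
#' @return 4x4 matrix mapping world points (column vectors).
#' @export
rigid_matrix <- function(tf) {
  R <- rotation_matrix(tf$rotation_deg)
  offset <- tf$center + tf$translation_mm - R %*% tf$center
  rbind(cbind(R, offset), c(0, 0, 0, 1))
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @return the inverse `rigid_transform` (same rotation centre).
#' @export
invert_rigid <- function(tf) {
  M <- solve(rigid_matrix(tf))
  matrix_to_rigid(M, center = tf$center)
}

#' Compose two rigid transforms (`a` after `b`)
#' @param a,b [rigid_transform()] objects.
#' @return the composition as a `rigid_transform` (centre taken from `a`).
#' @export
compose_rigid <- function(a, b) {
  matrix_to_rigid(rigid_matrix(a) %*% rigid_matrix(b), center = a$center)
}

matrix_to_rigid <- function(M, center = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  beta <- asin(max(-1, min(1, -R[3, 1])))
  alpha <- atan2(R[3, 2], R[3, 3])
  gamma <- atan2(R[2, 1], R[1, 1])
  rot <- c(alpha, beta, gamma) * 180 / pi
  t <- M[1:3, 4] - (center - R %*% center)
  rigid_transform(rot, as.numeric(t), center)
}

#' Trilinear sampling of a volume at world points
#'
#' Points outside the source grid return 0 with `inside = FALSE` (out-of-field
#' mask), matching the package's resampling convention.
#'
#' @param vol a [volume()].
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return list with `values` (length n) and `inside` (logical length n).
#' @export
sample_trilinear <- function(vol, pts) {
  dm <- dim(vol$values)
  sp <- diag(vol$affine)[1:3]
  org <- vol$affine[1:3, 4]
  # continuous 1-based voxel coordinates
  cx <- (pts[, 1] - org[1]) / sp[1] + 1
  cy <- (pts[, 2] - org[2]) / sp[2] + 1
  cz <- (pts[, 3] - org[3]) / sp[3] + 1
  inside <- cx >= 1 & cx <= dm[1] & cy >= 1 & cy <= dm[2] &
    cz >= 1 & cz <= dm[3]
  cx <- pmin(pmax(cx, 1), dm[1])
  cy <- pmin(pmax(cy, 1), dm[2])
  cz <- pmin(pmax(cz, 1), dm[3])
  x0 <- pmin(floor(cx), dm[1] - 1); y0 <- pmin(floor(cy), dm[2] - 1)
  z0 <- pmin(floor(cz), dm[3] - 1)
  fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
  v <- vol$values
  idx <- function(i, j, k) v[cbind(i, j, k)]
  val <-
    idx(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    idx(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    idx(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz) +
    idx(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz +
    idx(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz) +
    idx(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz +
    idx(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz +
    idx(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
  val[!inside] <- 0
  list(values = val, inside = inside)
}

#' Resample a volume onto a reference grid through a rigid transform
#'
#' The output voxel at world position `x` takes the value of `moving` at
#' `T(x)`; `T = identity` therefore regrids `moving` onto `reference`.
#'
#' @param moving a [volume()] supplying intensities.
#' @param reference a [volume()] supplying the target grid.
#' @param tf a [rigid_transform()] mapping reference-space points into
#'   moving-space points.
#' @return list with `volume` (resampled on the reference grid) and `inside`
#'   (logical array flagging voxels whose sample fell inside `moving`).
#' @export
resample_rigid <- function(moving, reference, tf = rigid_transform()) {
  pts <- grid_world(reference)
  M <- rigid_matrix(tf)
  tp <- pts %*% t(M[1:3, 1:3]) +
    matrix(M[1:3, 4], nrow(pts), 3, byrow = TRUE)
  s <- sample_trilinear(moving, tp)
  out <- volume(array(s$values, dim(reference$values)),
                reference$voxel_size, reference$affine)
  list(volume = out, inside = array(s$inside, dim(reference$values)))
}

#' Rigid co-registration by mean-squared-difference minimisation
#'
#' `mode = "identity"` (the default used when the generator produces both
#' contrasts on one grid) returns the exact identity transform and simply
#' regrids. `mode = "optimize"` minimises the mean squared intensity
#' difference between `fixed` and the resampled `moving` over the 6 rigid
#' parameters with derivative-free Nelder-Mead search from several starting
#' points; intended for same-contrast pairs.
#'
#' @param moving,fixed [volume()] objects with overlapping fields of view.
#' @param mode `"identity"` or `"optimize"`.
#' @param subsample integer stride applied to the fixed grid while
#'   optimising (final resampling is always at full resolution).
#' @param starts list of numeric length-6 starting parameter vectors
#'   (3 rotations deg, 3 translations mm); the identity is always included.
#' @return list with `transform` (a [rigid_transform()]), `volume` (moving
#'   resampled onto the fixed grid) and `mse`.
#' @export
register_rigid <- function(moving, fixed, mode = c("identity", "optimize"),
                           subsample = 2L, starts = list()) {
  mode <- match.arg(mode)
  stopifnot_volume(moving, "moving"); stopifnot_volume(fixed, "fixed")
  if (mode == "identity") {
    tf <- rigid_transform()
    rs <- resample_rigid(moving, fixed, tf)
    if (!any(rs$inside)) stop("no overlap between volumes")
    return(list(transform = tf, volume = rs$volume,
                mse = mean((rs$volume$values - fixed$values)^2)))
  }
  dm <- dim(fixed$values)
  keep <- array(FALSE, dm)
  keep[seq(1, dm[1], by = subsample), seq(1, dm[2], by = subsample),
       seq(1, dm[3], by = subsample)] <- TRUE
  pts <- grid_world(fixed)[as.vector(keep), , drop = FALSE]
  fv <- fixed$values[keep]
  objective <- function(par) {
    M <- rigid_matrix(rigid_transform(par[1:3], par[4:6]))
    tp <- pts %*% t(M[1:3, 1:3]) + matrix(M[1:3, 4], nrow(pts), 3,
                                          byrow = TRUE)
    s <- sample_trilinear(moving, tp)
    if (!any(s$inside)) return(.Machine$double.xmax)
    mean((s$values - fv)^2)
  }
  starts <- c(list(rep(0, 6)), starts)
  best <- NULL
  for (p0 in starts) {
    fit <- stats::optim(p0, objective, method = "Nelder-Mead",
                        control = list(maxit = 600, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # polish from the best start
  best <- stats::optim(best$par, objective, method = "Nelder-Mead",
                       control = list(maxit = 600, reltol = 1e-12))
  tf <- rigid_transform(best$par[1:3], best$par[4:6])
  rs <- resample_rigid(moving, fixed, tf)
  if (!any(rs$inside)) stop("no overlap between volumes after transform")
  list(transform = tf, volume = rs$volume, mse = best$value)
}

#' Serialize / read a rigid transform as a 6-number text record
#' @param tf a [rigid_transform()].
#' @param path output file.
#' @return `path` invisibly / a `rigid_transform`.
#' @export
write_rigid <- function(tf, path) {
  writeLines(paste(format(c(tf$rotation_deg, tf$translation_mm),
                          digits = 17), collapse = " "), path)
  invisible(path)
}

#' @rdname write_rigid
#' @export
read_rigid <- function(path) {
  v <- scan(path, quiet = TRUE)
  if (length(v) != 6) stop("rigid transform record must hold 6 numbers")
  rigid_transform(v[1:3], v[4:6])
}
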