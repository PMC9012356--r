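#' 3D image volume
#'
#' Lightweight container for a 3D intensity grid with a voxel-to-world affine.
#' World coordinates are RAS millimetres; voxel indices are 0-based, and the
#' affine maps voxel index `(i, j, k, 1)` to world `(x, y, z, 1)`. Volumes
#' created by this package use diagonal affines (axis-aligned grids); rigid
#' motion is represented separately by [rigid_transform()].
#'
#' @param values numeric 3D array of intensities (finite).
#' @param voxel_size numeric length-3 positive voxel spacing in mm.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to an RAS grid
#'   with the world origin at the grid centre.
#' @return an object of class `volume` with fields `values`, `affine`,
#'   `voxel_size`.
#' @export
volume <- function(values, voxel_size = c(1, 1, 1), affine = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stop("volume intensities must be finite")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive spacings (mm)")
  if (is.null(affine))
    affine <- centered_affine(dim(values), voxel_size)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("`affine` must be an invertible 4x4 matrix")
  structure(list(values = values, affine = affine, voxel_size = voxel_size),
            class = "volume")
}

# RAS affine with world origin at the centre of the voxel grid
centered_affine <- function(dm, voxel_size) {
  origin <- -(dm - 1) / 2 * voxel_size
  aff <- rbind(cbind(diag(voxel_size), origin), c(0, 0, 0, 1))
  dimnames(aff) <- NULL
  aff
}

#' @export
print.volume <- function(x, ...) {
  dm <- dim(x$values)
  cat(sprintf("<volume> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              dm[1], dm[2], dm[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$values)

is_volume <- function(x) inherits(x, "volume")

stopifnot_volume <- function(x, what = "volume") {
  if (!is_volume(x)) stop(sprintf("expected a `volume` for %s", what))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  all(dim(a$values) == dim(b$values)) &&
    max(abs(a$affine - b$affine)) < tol
}

require_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("volumes are not on the same grid")
  invisible(TRUE)
}

#' World coordinates of every voxel along one axis
#'
#' For the diagonal affines used throughout the package this gives the world
#' (mm) coordinate of voxel centres along axis `axis`.
#' @param vol a [volume()].
#' @param axis integer 1..3.
#' @return numeric vector of length `dim(vol)[axis]`.
#' @keywords internal
axis_world <- function(vol, axis) {
  n <- dim(vol$values)[axis]
  vol$affine[axis, axis] * (seq_len(n) - 1) + vol$affine[axis, 4]
}

# n x 3 matrix of world coordinates for all voxels (index order = R array order)
grid_world <- function(vol) {
  dm <- dim(vol$values)
  xs <- axis_world(vol, 1); ys <- axis_world(vol, 2); zs <- axis_world(vol, 3)
  cbind(rep(xs, times = dm[2] * dm[3]),
        rep(rep(ys, each = dm[1]), times = dm[3]),
        rep(zs, each = dm[1] * dm[2]))
}

#' Read a NIfTI-1 volume
#'
#' Accepts plain `.nii` and gzipped `.nii.gz` files; the data array and the
#' stored affine (sform preferred) round-trip losslessly through
#' [write_volume()].
#'
#' @param path path to a NIfTI-1 file.
#' @return a [volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop(sprintf("malformed NIfTI file '%s': %s",
                                 path, conditionMessage(e))))
  if (length(dim(img)) != 3L) stop("expected a 3D NIfTI volume")
  arr <- array(as.numeric(img), dim(img))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  vox <- RNifti::pixdim(img)[1:3]
  volume(arr, voxel_size = vox, affine = aff)
}

#' Write a NIfTI-1 volume
#'
#' @param vol a [volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot_volume(vol)
  arr <- structure(vol$values, pixdim = vol$voxel_size,
                   pixunits = c("mm", "s"))
  img <- RNifti::asNifti(arr, datatype = "double")
  aff <- structure(vol$affine, code = 2L)
  RNifti::`qform<-`(img, aff) -> img
  RNifti::`sform<-`(img, aff) -> img
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
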