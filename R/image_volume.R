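#' 3D CT image volume
#'
#' An `image_volume` is a 3D scalar grid of CT intensities in Hounsfield
#' units together with its physical geometry: per-axis voxel size (mm) and
#' the physical position of voxel (1,1,1) (mm, world frame).  Voxel index
#' `i` (0-based internally) maps to the physical point
#' `origin + i * spacing`; the world frame is axis-aligned (no oblique
#' direction cosines).  Air/background is -1000 HU.
#'
#' @param voxels 3D numeric array of intensities (HU).
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param origin numeric length-3, physical position of the first voxel (mm).
#' @param modality one of `"kVCT"`, `"MVCT"`, `"synthetic"`.
#' @return An object of class `image_volume`.
#' @examples
#' v <- image_volume(array(-1000, c(8, 8, 4)), spacing = c(1, 1, 4))
#' dim(v$voxels)
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                         modality = c("synthetic", "kVCT", "MVCT")) {
  modality <- match.arg(modality)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  storage.mode(voxels) <- "double"
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 modality = modality),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume [%s]> %d x %d x %d voxels @ %.3f x %.3f x %.3f mm\n",
              x$modality, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm; HU range [%.0f, %.0f]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

is_image_volume <- function(x) inherits(x, "image_volume")

stopifnot_image <- function(x, arg = deparse(substitute(x))) {
  if (!is_image_volume(x))
    stop(sprintf("`%s` must be an image_volume", arg), call. = FALSE)
  invisible(x)
}

img_dim <- function(img) dim(img$voxels)

#' Physical extent of a volume along one axis
#'
#' Returns the half-open physical interval covered by the voxels of `img`
#' along `axis`, measured from the first voxel's leading face to the last
#' voxel's trailing face (voxel centers sit at `origin + i * spacing`).
#'
#' @param img an [image_volume()].
#' @param axis axis index 1..3.
#' @return numeric length-2 `(lo, hi)` in mm.
#' @export
physical_extent <- function(img, axis = 3L) {
  stopifnot_image(img)
  n <- img_dim(img)[axis]
  lo <- img$origin[axis] - img$spacing[axis] / 2
  c(lo, lo + n * img$spacing[axis])
}

#' Voxel center coordinates along an axis
#' @inheritParams physical_extent
#' @return numeric vector of physical coordinates (mm).
#' @export
slice_centers <- function(img, axis = 3L) {
  stopifnot_image(img)
  img$origin[axis] + (seq_len(img_dim(img)[axis]) - 1) * img$spacing[axis]
}

#' Physical coordinates of all voxel centers
#'
#' @param img an [image_volume()] (or anything with voxels/spacing/origin).
#' @return an `prod(dim)` x 3 matrix of mm coordinates, in array order
#'   (first axis fastest).
#' @export
voxel_centers <- function(img) {
  d <- img_dim(img)
  xs <- img$origin[1] + (seq_len(d[1]) - 1) * img$spacing[1]
  ys <- img$origin[2] + (seq_len(d[2]) - 1) * img$spacing[2]
  zs <- img$origin[3] + (seq_len(d[3]) - 1) * img$spacing[3]
  cbind(rep(xs, times = d[2] * d[3]),
        rep(rep(ys, each = d[1]), times = d[3]),
        rep(zs, each = d[1] * d[2]))
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(img_dim(a), img_dim(b)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Binary mask sharing the geometry of a parent volume
#'
#' @param voxels 3D array coercible to 0/1.
#' @param parent the [image_volume()] whose geometry the mask inherits.
#' @return An object of class `mask` (also an `image_volume` structurally).
#' @export
new_mask <- function(voxels, parent) {
  stopifnot_image(parent)
  if (!identical(dim(voxels), img_dim(parent)))
    stop("mask dimensions must match the parent image", call. = FALSE)
  v <- array(as.integer(voxels != 0), dim = dim(voxels))
  structure(list(voxels = v, spacing = parent$spacing, origin = parent$origin),
            class = "mask")
}

#' @export
print.mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<mask> %d x %d x %d voxels, %d foreground (%.1f%%)\n",
              d[1], d[2], d[3], sum(x$voxels),
              100 * mean(x$voxels)))
  invisible(x)
}

is_mask <- function(x) inherits(x, "mask")

stopifnot_mask <- function(x, arg = deparse(substitute(x))) {
  if (!is_mask(x)) stop(sprintf("`%s` must be a mask", arg), call. = FALSE)
  invisible(x)
}

#' Number of foreground voxels and voxel volume
#' @param m a [new_mask()] object.
#' @return scalar voxel volume in mm^3.
#' @export
voxel_volume <- function(m) prod(m$spacing)
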