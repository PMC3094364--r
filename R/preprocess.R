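#' Pre-processing configuration
#'
#' Controls the three pre-processing steps applied before registration:
#' couch suppression, body masking, and axial cropping of the reference to
#' the partner's imaged extent.
#'
#' @param body_threshold HU threshold separating patient tissue from air;
#'   must lie in (-1000, 0).  Default -400 HU, standard CT body-masking
#'   practice.
#' @param couch_clearance logical; when `TRUE`, above-threshold connected
#'   components whose centroid lies in the posterior 15% band of the y
#'   extent (where the treatment couch sits) and that are detached from the
#'   largest component are suppressed before body selection.
#' @param background_fill HU value written outside the body (default -1000,
#'   air).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(body_threshold = -400, couch_clearance = TRUE,
                              background_fill = -1000) {
  if (!is.numeric(body_threshold) || body_threshold <= -1000 ||
      body_threshold >= 0)
    stop("`body_threshold` must lie in (-1000, 0) HU", call. = FALSE)
  structure(list(body_threshold = body_threshold,
                 couch_clearance = isTRUE(couch_clearance),
                 background_fill = background_fill),
            class = "preprocess_config")
}

#' Extract the patient body mask
#'
#' Thresholds the volume at `cfg$body_threshold`, suppresses couch-like
#' detached components in the posterior y band, keeps the largest remaining
#' 3D connected component (6-connectivity) and fills holes slice by slice
#' (2D, axial), so that low-density interior structures such as the lungs
#' belong to the body.
#'
#' @param img an [image_volume()], HU calibrated.
#' @param cfg a [preprocess_config()].
#' @return A body [new_mask()] (single connected component).
#' @export
extract_body_mask <- function(img, cfg = preprocess_config()) {
  stopifnot_image(img)
  fg <- img$voxels > cfg$body_threshold
  if (!any(fg))
    stop("degenerate input: no voxel above the body threshold", call. = FALSE)
  lab <- cpp_label3d(array(as.integer(fg), dim(fg)), dim(fg))
  sizes <- tabulate(lab[lab > 0L])
  if (cfg$couch_clearance && length(sizes) > 1L) {
    # posterior 15% band of the y extent hosts the treatment couch
    d <- img_dim(img)
    ymin <- 0.85 * (d[2] - 1)
    yidx <- slice.index(lab, 2) - 1
    main <- which.max(sizes)
    for (l in seq_along(sizes)) {
      if (l == main) next
      cy <- mean(yidx[lab == l])
      if (cy >= ymin) fg[lab == l] <- FALSE
    }
    lab <- cpp_label3d(array(as.integer(fg), dim(fg)), dim(fg))
    sizes <- tabulate(lab[lab > 0L])
  }
  body <- lab == which.max(sizes)
  body <- fill_holes_2d(body)
  new_mask(body, img)
}

# per-axial-slice 2D hole filling
fill_holes_2d <- function(m) {
  d <- dim(m)
  out <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    sl <- matrix(as.integer(m[, , k]), d[1], d[2])
    out[, , k] <- EBImage::fillHull(sl) > 0
  }
  out
}

#' Replace voxels outside the body with background
#'
#' Idempotent: applying it twice equals applying it once.
#'
#' @param img an [image_volume()].
#' @param body a body [new_mask()] with the same geometry.
#' @param cfg a [preprocess_config()] supplying `background_fill`.
#' @return The masked [image_volume()].
#' @export
mask_background <- function(img, body, cfg = preprocess_config()) {
  stopifnot_image(img)
  stopifnot_mask(body)
  if (!same_geometry(img, body))
    stop("image and body mask geometry differ", call. = FALSE)
  v <- img$voxels
  v[body$voxels == 0L] <- cfg$background_fill
  image_volume(v, img$spacing, img$origin, img$modality)
}

#' Crop the reference axially to the partner's imaged extent
#'
#' Keeps the reference slices whose physical z center falls inside the
#' partner's half-open physical z interval, so that metric samples do not
#' fall outside the partner's (smaller) field of view.  In-plane geometry is
#' never altered.
#'
#' @param reference the [image_volume()] to crop (typically the kVCT).
#' @param partner the volume whose z extent defines the crop (typically the
#'   MVCT).
#' @return The cropped reference [image_volume()].
#' @export
crop_axial_to_overlap <- function(reference, partner) {
  stopifnot_image(reference)
  stopifnot_image(partner)
  ext <- physical_extent(partner, 3L)
  centers <- slice_centers(reference, 3L)
  keep <- centers >= ext[1] & centers < ext[2]
  if (!any(keep))
    stop("degenerate input: no axial overlap between reference and partner",
         call. = FALSE)
  idx <- range(which(keep))
  v <- reference$voxels[, , idx[1]:idx[2], drop = FALSE]
  org <- reference$origin
  org[3] <- centers[idx[1]]
  image_volume(v, reference$spacing, org, reference$modality)
}

#' Separable Gaussian smoothing
#'
#' Gaussian filtering with a per-axis width parameter (standard deviation)
#' expressed in voxels; a width of 0 on an axis leaves that axis unfiltered.
#' The kernel is truncated at 3 standard deviations and boundaries are
#' handled by edge replication, so constant images are preserved exactly.
#'
#' @param img an [image_volume()].
#' @param kernel_voxels numeric length-3 (or scalar), nonnegative widths.
#' @return The smoothed [image_volume()].
#' @export
gaussian_smooth <- function(img, kernel_voxels) {
  stopifnot_image(img)
  k <- rep_len(as.numeric(kernel_voxels), 3L)
  if (any(!is.finite(k)) || any(k < 0))
    stop("`kernel_voxels` must be nonnegative", call. = FALSE)
  if (all(k == 0)) return(img)
  v <- cpp_gauss_smooth(img$voxels, img_dim(img), k)
  image_volume(v, img$spacing, img$origin, img$modality)
}
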