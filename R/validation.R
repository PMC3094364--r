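#' Border-trimmed correlation coefficient
#'
#' Pearson correlation of voxel intensities between the fixed and the
#' registered image over their common grid, excluding a border of
#' `border_xy` voxels on each side in x and y and `border_z` slices at each
#' z end.  The border exclusion removes areas interpolated from outside the
#' image volume, which carry no reliable information.  A linear relation
#' between the two images gives |CC| = 1.
#'
#' @param fixed the reference [image_volume()].
#' @param registered the registered [image_volume()] on the same geometry.
#' @param border_xy voxels stripped from each x and y side (default 30).
#' @param border_z slices stripped from each z end (default 2).
#' @return The correlation coefficient (dimensionless, in \[-1, 1\]).
#' @export
correlation_coefficient <- function(fixed, registered, border_xy = 30,
                                    border_z = 2) {
  stopifnot_image(fixed)
  stopifnot_image(registered)
  if (!same_geometry(fixed, registered))
    stop("fixed and registered images must share a geometry", call. = FALSE)
  d <- img_dim(fixed)
  ix <- (border_xy + 1):(d[1] - border_xy)
  iy <- (border_xy + 1):(d[2] - border_xy)
  iz <- (border_z + 1):(d[3] - border_z)
  if (border_xy < 0 || border_z < 0 || length(ix) < 1 || ix[1] > ix[length(ix)] ||
      d[1] - 2 * border_xy < 1 || d[2] - 2 * border_xy < 1 ||
      d[3] - 2 * border_z < 1)
    stop("interior region is empty after border removal", call. = FALSE)
  a <- as.numeric(fixed$voxels[ix, iy, iz])
  b <- as.numeric(registered$voxels[ix, iy, iz])
  if (sd(a) == 0 || sd(b) == 0)
    stop("undefined CC: constant interior in one of the images", call. = FALSE)
  cor(a, b)
}

#' Map landmarks through a registration transform
#'
#' Applies [transform_point()] to each landmark of a reference-frame
#' (kVCT) set, yielding their positions in the moving (MVCT) frame.
#' Landmarks falling outside the transform's domain are excluded from the
#' output and listed in the `excluded` attribute rather than silently
#' dropped.
#'
#' @param marks a [landmark_set()] in the kVCT frame.
#' @param T a [composite_transform()] or [rigid_transform()].
#' @return A [landmark_set()] in the MVCT frame (attribute `excluded`
#'   holds the labels of out-of-domain landmarks, if any).
#' @export
transform_landmarks <- function(marks, T) {
  T <- as_composite(T)
  p <- landmark_matrix(marks)
  ok <- rep(TRUE, nrow(p))
  if (!is.null(T$bspline)) {
    ok <- as.logical(cpp_bspline_inside(T$bspline$grid_origin,
                                        T$bspline$grid_spacing,
                                        T$bspline$grid_size, p))
  }
  q <- matrix(NA_real_, nrow(p), 3L)
  if (any(ok)) q[ok, ] <- transform_point(T, p[ok, , drop = FALSE])
  out <- landmark_set(marks$label[ok], q[ok, 1], q[ok, 2], q[ok, 3],
                      frame = "MVCT")
  attr(out, "excluded") <- marks$label[!ok]
  out
}

#' Target registration error
#'
#' Residual misalignment between transformed landmarks and their positions
#' independently identified in the target image: the per-landmark Euclidean
#' distance in mm, summarised by mean, sample standard deviation and
#' maximum.  Only labels common to both sets are compared.
#'
#' @param transformed a [landmark_set()] (typically from
#'   [transform_landmarks()]).
#' @param reference the [landmark_set()] of target-frame positions.
#' @return An object of class `tre`: a list with `per_landmark` (tibble of
#'   label and `tre_mm`), `mean`, `sd`, `max` and `n`.
#' @export
target_registration_error <- function(transformed, reference) {
  common <- intersect(transformed$label, reference$label)
  if (length(common) < 1L)
    stop("no common landmark labels between the two sets", call. = FALSE)
  a <- landmark_matrix(transformed[match(common, transformed$label), ])
  b <- landmark_matrix(reference[match(common, reference$label), ])
  d <- sqrt(rowSums((a - b)^2))
  structure(list(per_landmark = tibble::tibble(label = common, tre_mm = d),
                 mean = mean(d),
                 sd = if (length(d) > 1L) sd(d) else NA_real_,
                 max = max(d), n = length(d)),
            class = "tre")
}

#' @export
print.tre <- function(x, ...) {
  cat(sprintf("<tre> n = %d: mean %.2f +/- %.2f mm, max %.2f mm\n",
              x$n, x$mean, x$sd, x$max))
  invisible(x)
}

#' Lung segmentation by slice-wise region growing
#'
#' Grows lung regions slice by slice under an intensity window
#' (default -1000 to -500 HU, for HU-calibrated kVCT and MVCT alike):
#' within each axial slice, in-window voxels form 2D connected regions;
#' regions reachable from the exterior air at the slice border are
#' discarded, regions intersecting the body are kept, and enclosed holes
#' (vessels) are filled in 2D.  The union over slices is the binary lung
#' volume.
#'
#' @param img an HU-calibrated [image_volume()].
#' @param low,high intensity window in HU.
#' @param body optional body [new_mask()]; computed by
#'   [extract_body_mask()] when absent.
#' @return A lung [new_mask()].
#' @export
segment_lungs_region_growing <- function(img, low = -1000, high = -500,
                                         body = NULL) {
  stopifnot_image(img)
  if (is.null(body)) body <- extract_body_mask(img)
  if (!same_geometry(img, body))
    stop("image and body mask geometry differ", call. = FALSE)
  d <- img_dim(img)
  out <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    sl <- img$voxels[, , k]
    w <- sl >= low & sl <= high
    if (!any(w)) next
    lab <- EBImage::bwlabel(matrix(as.integer(w), d[1], d[2]))
    border <- unique(c(lab[1, ], lab[d[1], ], lab[, 1], lab[, d[2]]))
    border <- border[border > 0]
    bsl <- body$voxels[, , k] > 0
    keep <- setdiff(unique(lab[lab > 0 & bsl]), border)
    if (length(keep) == 0L) next
    kept <- matrix(as.integer(lab %in% keep), d[1], d[2])
    out[, , k] <- EBImage::fillHull(kept) > 0
  }
  if (!any(out))
    stop("empty segmentation: no lung-range region found inside the body",
         call. = FALSE)
  new_mask(out, img)
}

#' Split a lung mask into left and right lungs
#'
#' Takes the two largest 3D connected components and assigns them left /
#' right by centroid x coordinate in patient orientation (x increasing
#' towards the patient's left).  When severe pathology merges the lungs
#' into a single component, the component is split by the mid-sagittal
#' plane of the body mask (or its own x centroid when no body is given).
#'
#' @param lungs a lung [new_mask()] from [segment_lungs_region_growing()].
#' @param body optional body [new_mask()] defining the mid-sagittal plane.
#' @param fuse_ratio a second component smaller than this fraction of the
#'   first is treated as noise, triggering the fused-lung plane split.
#' @return A list with elements `left` and `right`, each a mask with
#'   attribute `side` (a component may be `NULL` with a warning when only
#'   one tiny lung is present).
#' @export
split_left_right <- function(lungs, body = NULL, fuse_ratio = 0.2) {
  stopifnot_mask(lungs)
  lab <- cpp_label3d(lungs$voxels, dim(lungs$voxels))
  sizes <- tabulate(lab[lab > 0L])
  if (length(sizes) == 0L) stop("empty lung mask", call. = FALSE)
  ord <- order(sizes, decreasing = TRUE)
  geom <- list(voxels = lungs$voxels, spacing = lungs$spacing,
               origin = lungs$origin)
  as_lung <- function(sel, side) {
    m <- new_mask(array(sel, dim(lungs$voxels)), structure(c(geom,
                  list(modality = "synthetic")), class = "image_volume"))
    attr(m, "side") <- side
    m
  }
  cx <- function(sel) {
    xi <- slice.index(lab, 1)
    mean(lungs$origin[1] + (xi[sel] - 1) * lungs$spacing[1])
  }
  if (length(sizes) >= 2L && sizes[ord[2]] >= fuse_ratio * sizes[ord[1]]) {
    s1 <- lab == ord[1]
    s2 <- lab == ord[2]
    if (cx(s1) >= cx(s2)) list(left = as_lung(s1, "left"),
                               right = as_lung(s2, "right"))
    else list(left = as_lung(s2, "left"), right = as_lung(s1, "right"))
  } else {
    main <- lab == ord[1]
    # fused lungs (or a single lung): split at the body's mid-sagittal plane
    mid <- if (!is.null(body)) {
      xi <- slice.index(body$voxels, 1)
      lungs$origin[1] + (mean(xi[body$voxels > 0]) - 1) * lungs$spacing[1]
    } else cx(main)
    xs <- lungs$origin[1] +
      (slice.index(lungs$voxels, 1) - 1) * lungs$spacing[1]
    lf <- main & xs >= mid
    rt <- main & xs < mid
    if (!any(lf) || !any(rt)) {
      warning("single lung component on one side of the mid-sagittal plane; ",
              "returning a single lung", call. = FALSE)
      side <- if (any(lf)) "left" else "right"
      out <- list(left = NULL, right = NULL)
      out[[side]] <- as_lung(main, side)
      return(out)
    }
    list(left = as_lung(lf, "left"), right = as_lung(rt, "right"))
  }
}

#' Restrict paired lung masks to the commonly imaged z interval
#'
#' Lung correspondence is always measured on the lung sub-region imaged in
#' both studies; this zeroes both masks outside the common axial interval.
#'
#' @param a,b lung [new_mask()]s.
#' @param fov_z physical z interval `(lo, hi)` in mm; defaults to the
#'   intersection of the two masks' grid extents.
#' @return A list with the two restricted masks.
#' @export
restrict_to_common_extent <- function(a, b, fov_z = NULL) {
  stopifnot_mask(a)
  stopifnot_mask(b)
  if (is.null(fov_z)) {
    ea <- mask_extent_z(a)
    eb <- mask_extent_z(b)
    fov_z <- c(max(ea[1], eb[1]), min(ea[2], eb[2]))
  }
  if (fov_z[2] <= fov_z[1])
    stop("empty common z extent", call. = FALSE)
  list(a = zero_outside_z(a, fov_z), b = zero_outside_z(b, fov_z))
}

mask_extent_z <- function(m) {
  n <- dim(m$voxels)[3]
  lo <- m$origin[3] - m$spacing[3] / 2
  c(lo, lo + n * m$spacing[3])
}

zero_outside_z <- function(m, fov_z) {
  zc <- m$origin[3] + (seq_len(dim(m$voxels)[3]) - 1) * m$spacing[3]
  keep <- zc >= fov_z[1] & zc < fov_z[2]
  v <- m$voxels
  v[, , !keep] <- 0L
  out <- m
  out$voxels <- v
  out
}

#' Lung volume in cubic millimetres
#'
#' The binary volume piled up from the per-slice contours: foreground voxel
#' count times voxel volume.
#'
#' @param m a [new_mask()].
#' @return Volume in mm^3.
#' @export
lung_volume <- function(m) {
  stopifnot_mask(m)
  sum(m$voxels) * voxel_volume(m)
}

#' Percent volume error between corresponding lung volumes
#'
#' `V_E = 100 * (V_CT - V_reg) / V_CT`: the signed percent discrepancy of
#' the registered-image lung volume relative to the reference (kVCT) lung
#' volume.
#'
#' @param v_ct reference lung volume (mm^3 or any consistent unit), > 0.
#' @param v_reg registered-image lung volume in the same unit.
#' @return Signed percent error.
#' @export
volume_error <- function(v_ct, v_reg) {
  if (any(v_ct <= 0)) stop("`v_ct` must be positive", call. = FALSE)
  100 * (v_ct - v_reg) / v_ct
}

mask_centroid <- function(m) {
  idx <- which(m$voxels > 0)
  if (length(idx) == 0L) stop("empty mask has no centroid", call. = FALSE)
  d <- dim(m$voxels)
  idx0 <- idx - 1L
  i <- idx0 %% d[1]
  j <- (idx0 %/% d[1]) %% d[2]
  k <- idx0 %/% (d[1] * d[2])
  c(m$origin[1] + mean(i) * m$spacing[1],
    m$origin[2] + mean(j) * m$spacing[2],
    m$origin[3] + mean(k) * m$spacing[3])
}

#' Centroid error between two binary volumes
#'
#' Euclidean distance (mm) between the physical-space centroids of the two
#' masks.
#'
#' @param a,b non-empty [new_mask()]s.
#' @return Distance in mm.
#' @export
centroid_error <- function(a, b) {
  stopifnot_mask(a)
  stopifnot_mask(b)
  sqrt(sum((mask_centroid(a) - mask_centroid(b))^2))
}

#' Jaccard overlap index
#'
#' `|A intersect B| / |A union B|` between two masks on the same geometry:
#' 1 for identical sets, 0 for disjoint ones.
#'
#' @param a,b [new_mask()]s sharing a geometry.
#' @return Overlap ratio in \[0, 1\].
#' @export
jaccard_index <- function(a, b) {
  stopifnot_mask(a)
  stopifnot_mask(b)
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop("masks must share a geometry", call. = FALSE)
  va <- a$voxels > 0
  vb <- b$voxels > 0
  uni <- sum(va | vb)
  if (uni == 0L)
    stop("Jaccard index undefined for two empty masks", call. = FALSE)
  sum(va & vb) / uni
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test between rigid-stage and elastic-stage
#' metric values.  Zero differences are dropped (Wilcoxon's rule) and tied
#' absolute differences receive average ranks.  The exact null distribution
#' is used for n <= 25 without ties; otherwise a normal approximation with
#' tie correction and continuity correction.
#'
#' @param rigid_values,elastic_values paired numeric vectors of equal
#'   length >= 5.
#' @return A list with `p_value`, `statistic` (V, the positive-rank sum),
#'   `n` (nonzero pairs) and `method`.
#' @export
wilcoxon_signed_rank <- function(rigid_values, elastic_values) {
  if (length(rigid_values) != length(elastic_values))
    stop("paired vectors must have equal length", call. = FALSE)
  if (length(rigid_values) < 5L)
    stop("at least 5 pairs are required", call. = FALSE)
  d <- elastic_values - rigid_values
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop("degenerate test: all paired differences are zero", call. = FALSE)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (!ties && n <= 25L) {
    p <- 2 * min(psignrank(V, n), 1 - psignrank(V - 1, n))
    p <- min(1, p)
    method <- "exact"
  } else if (ties && n <= 15L) {
    # midranks break the psignrank lattice; enumerate all 2^n sign patterns
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    V_all <- as.numeric(signs %*% r)
    mu <- n * (n + 1) / 4
    p <- mean(abs(V_all - mu) >= abs(V - mu) - 1e-12)
    method <- "exact (enumeration)"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(p_value = p, statistic = V, n = n, method = method)
}
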