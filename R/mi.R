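#' Mutual-information metric configuration
#'
#' @param n_bins joint-histogram bins per image (>= 8); 50 is the canonical
#'   choice for the Mattes-form metric.
#' @param sample_fraction percentage of fixed-image body voxels used as
#'   metric samples, in (0, 100].
#' @param seed RNG seed making the stochastic sampling reproducible.
#' @param min_samples lower guard on usable samples: the metric aborts when
#'   fewer than `min(min_samples, 25%` of the drawn points`)` map inside the
#'   moving image, which signals excessive misalignment or over-cropping.
#' @return An `mi_config` list.
#' @export
mi_config <- function(n_bins = 50, sample_fraction = 10, seed = 2011,
                      min_samples = 1000) {
  if (n_bins < 8) stop("`n_bins` must be >= 8", call. = FALSE)
  if (sample_fraction <= 0 || sample_fraction > 100)
    stop("`sample_fraction` must lie in (0, 100]", call. = FALSE)
  structure(list(n_bins = as.integer(n_bins),
                 sample_fraction = sample_fraction,
                 seed = as.integer(seed),
                 min_samples = as.integer(min_samples)),
            class = "mi_config")
}

# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Draw metric sample points from the fixed image
#'
#' Uniform random draw without replacement of `round(fraction/100 * n)`
#' voxel centers inside the body mask; reproducible given `seed`.  With
#' `fraction = 100` all body voxel centers are returned in array order.
#'
#' @param fixed the fixed [image_volume()].
#' @param body a body [new_mask()] on the same geometry.
#' @param fraction percentage of body voxels to draw, in (0, 100].
#' @param seed RNG seed.
#' @param min_samples degenerate-sampling guard on the draw size.
#' @return An n x 3 matrix of physical points (mm) with attribute
#'   `voxel_index` giving the linear voxel index of each point.
#' @export
sample_fixed_points <- function(fixed, body, fraction, seed,
                                min_samples = 1L) {
  stopifnot_image(fixed)
  stopifnot_mask(body)
  if (!same_geometry(fixed, body))
    stop("fixed image and body mask geometry differ", call. = FALSE)
  if (fraction <= 0 || fraction > 100)
    stop("`fraction` must lie in (0, 100]", call. = FALSE)
  idx <- which(body$voxels == 1L)
  n <- round(fraction / 100 * length(idx))
  if (n < min_samples)
    stop(sprintf("degenerate sampling: %d points drawn, %d required",
                 n, min_samples), call. = FALSE)
  sel <- if (n == length(idx)) idx else
    with_seed(seed, sort(sample(idx, n, replace = FALSE)))
  pts <- linear_index_to_points(fixed, sel)
  attr(pts, "voxel_index") <- sel
  pts
}

linear_index_to_points <- function(img, idx) {
  d <- img_dim(img)
  idx0 <- idx - 1L
  i <- idx0 %% d[1]
  j <- (idx0 %/% d[1]) %% d[2]
  k <- idx0 %/% (d[1] * d[2])
  cbind(img$origin[1] + i * img$spacing[1],
        img$origin[2] + j * img$spacing[2],
        img$origin[3] + k * img$spacing[3])
}

# shared sample-count guard
usable_threshold <- function(cfg, n_drawn) {
  min(cfg$min_samples, ceiling(0.25 * n_drawn))
}

#' Mattes-form mutual information and its gradient
#'
#' Evaluates the negative mutual information between fixed-image samples and
#' the moving image at their transformed positions.  The joint distribution
#' is a Parzen estimate with a zero-order window along the fixed intensity
#' axis and a cubic B-spline window along the moving axis, so the metric is
#' differentiable in the transform parameters.  Samples mapping outside the
#' moving domain are dropped and the distribution renormalised over the
#' remainder.
#'
#' @param fixed,moving [image_volume()]s (fixed supplies sample intensities,
#'   moving is interpolated at mapped positions).
#' @param transform a [composite_transform()] or [rigid_transform()].
#' @param points sample points from [sample_fixed_points()].
#' @param cfg an [mi_config()].
#' @param wrt which free parameters to differentiate with respect to:
#'   `"none"` (value only), `"rigid"` (6 parameters: three Euler angles,
#'   three translations) or `"bspline"` (the coefficient lattice).
#' @return A list with `value` (-MI), `gradient` (`NULL`, length-6 vector,
#'   or coefficient-shaped array), and `n_used` (samples inside the moving
#'   domain).
#' @export
mattes_mi_value_gradient <- function(fixed, moving, transform, points,
                                     cfg = mi_config(),
                                     wrt = c("none", "rigid", "bspline")) {
  wrt <- match.arg(wrt)
  stopifnot_image(fixed)
  stopifnot_image(moving)
  T <- as_composite(transform)
  points <- as_point_matrix(points)
  idx <- attr(points, "voxel_index")
  fvals <- if (!is.null(idx)) fixed$voxels[idx] else
    cpp_trilinear(fixed$voxels, img_dim(fixed), fixed$spacing, fixed$origin,
                  points, -1000, FALSE)$values
  mapped <- transform_point(T, points)
  res <- mattes_mi_core(fvals, mapped, moving, cfg$n_bins,
                        range(fvals), range(moving$voxels),
                        want_grad = wrt != "none")
  thr <- usable_threshold(cfg, nrow(points))
  if (res$n_used < thr)
    stop(sprintf(paste0("degenerate sampling: only %d of %d samples map ",
                        "inside the moving image (>= %d required); the ",
                        "images may be grossly misaligned or over-cropped"),
                 res$n_used, nrow(points), thr), call. = FALSE)
  grad <- switch(wrt,
                 none = NULL,
                 rigid = chain_rigid_gradient(res$gradient, points, T$rigid),
                 bspline = {
                   if (is.null(T$bspline))
                     stop("transform has no B-spline part", call. = FALSE)
                   cpp_bspline_scatter(T$bspline$grid_origin,
                                       T$bspline$grid_spacing,
                                       T$bspline$grid_size, points,
                                       res$gradient)
                 })
  list(value = res$value, gradient = grad, n_used = res$n_used)
}

mattes_mi_core <- function(fvals, mapped, moving, n_bins, frange, mrange,
                           want_grad) {
  cpp_mattes_mi(fvals, mapped, moving$voxels, img_dim(moving),
                moving$spacing, moving$origin, as.integer(n_bins),
                frange[1], frange[2], mrange[1], mrange[2], want_grad)
}

# chain d(-MI)/d(mapped point) to the 6 rigid parameters
chain_rigid_gradient <- function(point_grad, points, rig) {
  g <- numeric(6)
  pc <- sweep(points, 2L, rig$center, "-")
  for (a in 1:3) {
    dR <- rotation_matrix_deriv(rig$rotation, a)
    dq <- pc %*% t(dR)
    g[a] <- sum(point_grad * dq)
  }
  g[4:6] <- colSums(point_grad)
  names(g) <- c("rx", "ry", "rz", "tx", "ty", "tz")
  g
}
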