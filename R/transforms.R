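#' Global rigid transformation
#'
#' Rotation (three Euler angles, applied Z then Y then X) about a fixed
#' center, followed by a translation:
#' `T(p) = R (p - center) + center + translation`.
#'
#' @param rotation numeric length-3 Euler angles in radians (rx, ry, rz).
#' @param translation numeric length-3 in mm.
#' @param center rotation center in mm.
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot (%.4f, %.4f, %.4f) rad; t (%.2f, %.2f, %.2f) mm\n",
              x$rotation[1], x$rotation[2], x$rotation[3],
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

rotation_matrix <- function(rotation) {
  cx <- cos(rotation[1]); sx <- sin(rotation[1])
  cy <- cos(rotation[2]); sy <- sin(rotation[2])
  cz <- cos(rotation[3]); sz <- sin(rotation[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# affine form T(p) = A p + b
rigid_affine <- function(rig) {
  A <- rotation_matrix(rig$rotation)
  b <- rig$center + rig$translation - A %*% rig$center
  list(A = A, b = as.numeric(b))
}

# derivative of the rotation matrix w.r.t. one Euler angle
rotation_matrix_deriv <- function(rotation, which) {
  cx <- cos(rotation[1]); sx <- sin(rotation[1])
  cy <- cos(rotation[2]); sy <- sin(rotation[2])
  cz <- cos(rotation[3]); sz <- sin(rotation[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  dRx <- matrix(c(0, 0, 0, 0, -sx, cx, 0, -cx, -sx), 3, 3)
  dRy <- matrix(c(-sy, 0, -cy, 0, 0, 0, cy, 0, -sy), 3, 3)
  dRz <- matrix(c(-sz, cz, 0, -cz, -sz, 0, 0, 0, 0), 3, 3)
  switch(which,
         Rz %*% Ry %*% dRx,
         Rz %*% dRy %*% Rx,
         dRz %*% Ry %*% Rx)
}

#' Invert a rigid transformation
#' @param rig a [rigid_transform()].
#' @return The inverse `rigid_transform` expressed with the same center.
#' @export
invert_rigid <- function(rig) {
  af <- rigid_affine(rig)
  Ai <- t(af$A)
  bi <- -Ai %*% af$b
  # recover Euler angles of the transposed matrix (ZYX convention)
  ry <- asin(-Ai[3, 1])
  rx <- atan2(Ai[3, 2], Ai[3, 3])
  rz <- atan2(Ai[2, 1], Ai[1, 1])
  tr <- as.numeric(bi) - rig$center + Ai %*% rig$center
  rigid_transform(c(rx, ry, rz), as.numeric(tr), rig$center)
}

#' Cubic B-spline free-form deformation lattice
#'
#' The displacement at a physical point is a tensor-product cubic B-spline
#' expansion over a regular grid of control-point coefficients (mm).  The
#' grid covers a physical domain plus the one-control-point cubic support
#' margin on every side; an all-zero coefficient lattice is exactly the zero
#' displacement.
#'
#' Constructed by [init_bspline_grid()] and refined by
#' [refine_bspline_grid()].
#'
#' @param grid_origin physical position of the first control point (mm).
#' @param grid_spacing per-axis control-point spacing (mm).
#' @param grid_size integer control points per axis.
#' @param coefficients numeric array `(n1, n2, n3, 3)` of displacement
#'   coefficients (mm); defaults to zeros.
#' @return A `bspline_transform` object.
#' @export
bspline_transform <- function(grid_origin, grid_spacing, grid_size,
                              coefficients = NULL) {
  grid_size <- as.integer(grid_size)
  if (is.null(coefficients))
    coefficients <- array(0, c(grid_size, 3L))
  if (!identical(dim(coefficients), c(grid_size, 3L)))
    stop("`coefficients` must have dim (grid_size, 3)", call. = FALSE)
  structure(list(grid_origin = as.numeric(grid_origin),
                 grid_spacing = as.numeric(grid_spacing),
                 grid_size = grid_size,
                 coefficients = coefficients),
            class = "bspline_transform")
}

#' @export
print.bspline_transform <- function(x, ...) {
  cat(sprintf("<bspline_transform> %d x %d x %d control points @ %.1f x %.1f x %.1f mm\n",
              x$grid_size[1], x$grid_size[2], x$grid_size[3],
              x$grid_spacing[1], x$grid_spacing[2], x$grid_spacing[3]))
  invisible(x)
}

#' Initialise a zero B-spline lattice over an image domain
#'
#' The control-point spacing is the largest value not exceeding
#' `spacing_mm` that divides the physical extent of the image (the span of
#' its voxel centers) into an integer number of intervals; one extra control
#' point is placed beyond each end so the cubic support covers the whole
#' domain.
#'
#' @param fixed the [image_volume()] whose domain the lattice must cover.
#' @param spacing_mm requested control-point spacing (scalar or length-3,
#'   mm, > 0).
#' @return A [bspline_transform()] with zero coefficients.
#' @export
init_bspline_grid <- function(fixed, spacing_mm) {
  stopifnot_image(fixed)
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(spacing_mm <= 0)) stop("`spacing_mm` must be > 0", call. = FALSE)
  d <- img_dim(fixed)
  L <- (d - 1) * fixed$spacing
  if (any(L <= 0))
    stop("degenerate input: image extent must exceed one voxel per axis",
         call. = FALSE)
  nint <- pmax(1L, as.integer(ceiling(L / spacing_mm - 1e-9)))
  sp <- L / nint
  bspline_transform(grid_origin = fixed$origin - sp,
                    grid_spacing = sp,
                    grid_size = nint + 4L)
}

bspline_domain <- function(B) {
  org <- B$grid_origin + B$grid_spacing
  L <- (B$grid_size - 4L) * B$grid_spacing
  list(origin = org, extent = L)
}

#' Displacement of a B-spline lattice at physical points
#'
#' @param B a [bspline_transform()].
#' @param p a length-3 point or an n x 3 matrix (mm).  Points must lie
#'   inside the lattice support.
#' @return An n x 3 matrix of displacements (mm).
#' @export
bspline_displacement <- function(B, p) {
  p <- as_point_matrix(p)
  cpp_bspline_eval(B$coefficients, B$grid_origin, B$grid_spacing, B$grid_size,
                   p, FALSE)
}

as_point_matrix <- function(p) {
  if (is.null(dim(p))) p <- matrix(as.numeric(p), ncol = 3L)
  if (ncol(p) != 3L) stop("points must have 3 columns", call. = FALSE)
  storage.mode(p) <- "double"
  p
}

#' Composite spatial transformation
#'
#' The registration's spatial model: a global rigid transformation plus a
#' local B-spline displacement, `T(p) = Rigid(p) + D(p)`, with `D` defined
#' on the fixed-image (reference) domain.  With an absent or all-zero
#' B-spline part, `T` reduces to the rigid map.
#'
#' @param rigid a [rigid_transform()].
#' @param bspline a [bspline_transform()] or `NULL`.
#' @return A `composite_transform` object.
#' @export
composite_transform <- function(rigid = rigid_transform(), bspline = NULL) {
  if (!inherits(rigid, "rigid_transform"))
    stop("`rigid` must be a rigid_transform", call. = FALSE)
  if (!is.null(bspline) && !inherits(bspline, "bspline_transform"))
    stop("`bspline` must be a bspline_transform or NULL", call. = FALSE)
  structure(list(rigid = rigid, bspline = bspline),
            class = "composite_transform")
}

#' @export
print.composite_transform <- function(x, ...) {
  cat("<composite_transform>\n  ")
  print(x$rigid)
  if (!is.null(x$bspline)) {
    cat("  ")
    print(x$bspline)
  } else cat("  (no elastic part)\n")
  invisible(x)
}

as_composite <- function(T) {
  if (inherits(T, "composite_transform")) return(T)
  if (inherits(T, "rigid_transform")) return(composite_transform(T))
  stop("expected a composite_transform or rigid_transform", call. = FALSE)
}

#' Apply a spatial transformation to physical points
#'
#' Maps reference-frame (kVCT) physical points into the moving-image (MVCT)
#' frame: `T(p) = Rigid(p) + D(p)`.  Points outside the B-spline lattice
#' support raise a domain error.
#'
#' @param T a [composite_transform()] or [rigid_transform()].
#' @param p a length-3 point or an n x 3 matrix (mm).
#' @return An n x 3 matrix of mapped points (a length-3 vector if `p` was).
#' @export
transform_point <- function(T, p) {
  vec_in <- is.null(dim(p))
  p <- as_point_matrix(p)
  T <- as_composite(T)
  af <- rigid_affine(T$rigid)
  q <- p %*% t(af$A)
  q <- sweep(q, 2L, af$b, "+")
  if (!is.null(T$bspline))
    q <- q + bspline_displacement(T$bspline, p)
  if (vec_in && nrow(q) == 1L) as.numeric(q) else q
}

#' Dense displacement field of a transformation
#'
#' Evaluates `T(p) - p` at every voxel center of a geometry.
#'
#' @param T a [composite_transform()] or [rigid_transform()].
#' @param geometry an [image_volume()] supplying the grid.
#' @return A numeric array `(nx, ny, nz, 3)` of displacements in mm.
#' @export
dense_displacement_field <- function(T, geometry) {
  stopifnot_image(geometry)
  p <- voxel_centers(geometry)
  q <- transform_point(T, p)
  array(q - p, c(img_dim(geometry), 3L))
}

#' Refine a B-spline lattice to a finer control-point spacing
#'
#' Builds a finer lattice over the same physical domain and fits its
#' coefficients so the displacement field of the input is reproduced (the
#' fit is a separable least-squares collocation on a dense tensor grid of
#' sample points, four per new interval per axis; dyadic refinements are
#' reproduced to numerical precision).
#'
#' @param B a [bspline_transform()].
#' @param new_spacing_mm requested spacing, strictly smaller than the
#'   current spacing.
#' @param max_points memory guard on the number of control points of the
#'   refined lattice.
#' @return The refined [bspline_transform()].
#' @export
refine_bspline_grid <- function(B, new_spacing_mm, max_points = 2e6) {
  new_spacing_mm <- rep_len(as.numeric(new_spacing_mm), 3L)
  if (any(new_spacing_mm <= 0))
    stop("`new_spacing_mm` must be positive", call. = FALSE)
  dom <- bspline_domain(B)
  nint_old <- B$grid_size - 4L
  # per-axis: refine to the requested spacing, never coarsen; an axis whose
  # extent already forces a spacing below the request keeps its grid
  nint <- pmax(nint_old,
               pmax(1L, as.integer(ceiling(dom$extent / new_spacing_mm - 1e-9))))
  if (all(nint == nint_old))
    stop("`new_spacing_mm` must be smaller than the current grid spacing",
         call. = FALSE)
  sp <- dom$extent / nint
  newB <- bspline_transform(grid_origin = dom$origin - sp,
                            grid_spacing = sp,
                            grid_size = nint + 4L)
  if (prod(newB$grid_size) > max_points)
    stop("refined grid exceeds the configured control-point budget",
         call. = FALSE)
  if (all(B$coefficients == 0)) return(newB)

  # sample positions: 4 per new interval per axis, plus the endpoint
  samp <- lapply(1:3, function(a) {
    n <- 4L * nint[a]
    dom$origin[a] + seq(0, dom$extent[a], length.out = n + 1L)
  })
  grid_pts <- as.matrix(expand.grid(samp[[1]], samp[[2]], samp[[3]],
                                    KEEP.OUT.ATTRS = FALSE))
  D <- cpp_bspline_eval(B$coefficients, B$grid_origin, B$grid_spacing,
                        B$grid_size, grid_pts, FALSE)
  m <- vapply(samp, length, 1L)
  Darr <- array(D, c(m, 3L))
  # 1D collocation matrices of the new lattice
  bas <- lapply(1:3, function(a) {
    u <- (samp[[a]] - newB$grid_origin[a]) / newB$grid_spacing[a]
    outer(u, seq_len(newB$grid_size[a]) - 1, function(uu, j) b3_weight(uu - j))
  })
  coef <- mode_solve(Darr, bas)
  newB$coefficients <- coef
  newB
}

b3_weight <- function(t) cpp_b3_kernel(as.numeric(t))

# successive per-mode least-squares solves of a separable collocation system
mode_solve <- function(arr, bas) {
  d <- dim(arr)
  for (a in 1:3) {
    perm <- c(a, setdiff(1:4, a))
    x <- aperm(arr, perm)
    dp <- dim(x)
    x <- matrix(x, nrow = dp[1])
    sol <- qr.coef(qr(bas[[a]]), x)
    sol[is.na(sol)] <- 0
    arr <- aperm(array(sol, c(ncol(bas[[a]]), dp[-1])), order(perm))
    dim(arr) <- replace(d, a, ncol(bas[[a]]))
    d <- dim(arr)
  }
  arr
}

#' Resample a moving image onto a reference grid
#'
#' Each reference voxel center `p` is mapped by the transformation and the
#' moving image is sampled there by trilinear interpolation; points mapping
#' outside the moving domain receive the background fill.  This produces
#' the "registered" image on the reference grid.
#'
#' @param moving the [image_volume()] to warp (typically the MVCT).
#' @param transform a [composite_transform()] or [rigid_transform()].
#' @param reference the [image_volume()] supplying the output grid.
#' @param fill out-of-domain fill value in HU.
#' @return The resampled [image_volume()] on the reference geometry.
#' @export
resample_to_reference <- function(moving, transform, reference, fill = -1000) {
  stopifnot_image(moving)
  stopifnot_image(reference)
  T <- as_composite(transform)
  af <- rigid_affine(T$rigid)
  use_b <- !is.null(T$bspline)
  v <- cpp_resample(moving$voxels, img_dim(moving), moving$spacing,
                    moving$origin, img_dim(reference), reference$spacing,
                    reference$origin, af$A, af$b, use_b,
                    if (use_b) T$bspline$coefficients else numeric(0),
                    if (use_b) T$bspline$grid_origin else numeric(3),
                    if (use_b) T$bspline$grid_spacing else numeric(3),
                    if (use_b) T$bspline$grid_size else integer(3),
                    fill)
  image_volume(v, reference$spacing, reference$origin, moving$modality)
}

#' @rdname resample_to_reference
#' @export
warp_moving_image <- function(moving, transform, reference, fill = -1000) {
  resample_to_reference(moving, transform, reference, fill)
}

#' Serialize a transformation to JSON
#'
#' Stores rigid parameters, lattice geometry and the coefficient array
#' (row-major over x, then y, then z, then component) in a plain JSON
#' document re-readable by [read_transform()].
#'
#' @param T a [composite_transform()] (or [rigid_transform()]).
#' @param path output file.
#' @export
write_transform <- function(T, path) {
  T <- as_composite(T)
  doc <- list(
    format = "mvctreg-transform-v1",
    axis_order = "x,y,z (first array axis fastest)",
    rigid = list(rotation_rad = T$rigid$rotation,
                 translation_mm = T$rigid$translation,
                 center_mm = T$rigid$center))
  if (!is.null(T$bspline)) {
    doc$bspline <- list(grid_origin_mm = T$bspline$grid_origin,
                        grid_spacing_mm = T$bspline$grid_spacing,
                        grid_size = T$bspline$grid_size,
                        coefficients_mm = as.numeric(T$bspline$coefficients))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a transformation written by [write_transform()]
#' @param path JSON file.
#' @return A [composite_transform()].
#' @export
read_transform <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "mvctreg-transform-v1"))
    stop(sprintf("'%s' is not a serialized transform", path), call. = FALSE)
  rig <- rigid_transform(doc$rigid$rotation_rad, doc$rigid$translation_mm,
                         doc$rigid$center_mm)
  bsp <- NULL
  if (!is.null(doc$bspline)) {
    gs <- as.integer(doc$bspline$grid_size)
    bsp <- bspline_transform(doc$bspline$grid_origin_mm,
                             doc$bspline$grid_spacing_mm, gs,
                             array(doc$bspline$coefficients_mm, c(gs, 3L)))
  }
  composite_transform(rig, bsp)
}
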