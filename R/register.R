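#' Rigid registration configuration
#'
#' Three-level multi-resolution schedule for the global rigid stage: an
#' image pyramid with per-level shrink factors (each capped so no axis
#' drops below 8 voxels) and matched Gaussian pre-smoothing, optimised by
#' regular-step gradient descent on the 6 rigid parameters.  The per-level
#' minimum step lengths (the convergence tolerances) decrease as
#' 1e-2, 5e-3, 2.5e-3 mm.
#'
#' @param shrink per-level pyramid shrink factors.
#' @param max_step,min_step per-level initial and terminal step lengths in
#'   scaled parameter space (mm).
#' @param max_iter iteration cap per level.
#' @param relaxation step-halving factor applied when a step fails to
#'   decrease the metric.
#' @param max_backtracks consecutive failed relaxations after which the
#'   level is declared non-convergent.
#' @param rot_scale parameter scaling: 1 radian of rotation is treated as
#'   `rot_scale` mm so rotations and translations are commensurate.
#' @param sample_percent per-level percentage of body voxels used by the
#'   metric.
#' @param n_bins,seed,min_samples see [mi_config()].
#' @param body_threshold HU threshold defining the sampling domain at each
#'   pyramid level.
#' @return A `rigid_config` list.
#' @export
rigid_config <- function(shrink = c(4, 2, 1),
                         max_step = c(4, 2, 1),
                         min_step = c(1e-2, 5e-3, 2.5e-3),
                         max_iter = 200L,
                         relaxation = 0.5,
                         max_backtracks = 25L,
                         rot_scale = 50,
                         sample_percent = c(100, 50, 25),
                         n_bins = 50L,
                         seed = 2011L,
                         min_samples = 1000L,
                         body_threshold = -400) {
  nl <- length(shrink)
  stopifnot(length(max_step) == nl, length(min_step) == nl,
            length(sample_percent) == nl)
  structure(list(shrink = shrink, max_step = max_step, min_step = min_step,
                 max_iter = as.integer(max_iter), relaxation = relaxation,
                 max_backtracks = as.integer(max_backtracks),
                 rot_scale = rot_scale, sample_percent = sample_percent,
                 n_bins = as.integer(n_bins), seed = as.integer(seed),
                 min_samples = as.integer(min_samples),
                 body_threshold = body_threshold),
            class = "rigid_config")
}

# smoothing + subsampled resample for one pyramid level
downsample_volume <- function(img, shrink) {
  shrink <- rep_len(shrink, 3L)
  d <- img_dim(img)
  s <- pmax(1, pmin(shrink, floor(d / 8)))
  if (all(s == 1)) return(img)
  sm <- gaussian_smooth(img, ifelse(s > 1, s / 2, 0))
  nd <- floor((d - 1) / s) + 1
  ref <- image_volume(array(0, nd), img$spacing * s, img$origin, img$modality)
  resample_to_reference(sm, rigid_transform(), ref)
}

#' Rigid registration by mutual information
#'
#' Estimates the global rigid transformation (rotation about the fixed
#' image's physical center plus translation) that aligns the moving image
#' to the fixed image.  A three-level image pyramid is used; at each level
#' the negative Mattes mutual information is minimised by regular-step
#' gradient descent with the level's step lengths: steps move against the
#' normalised metric gradient, are halved whenever the metric fails to
#' decrease, and the level terminates when the step length falls below the
#' level's minimum.
#'
#' @param fixed,moving pre-processed [image_volume()]s (couch removed,
#'   background at -1000 HU, fixed cropped to the moving z extent).
#' @param init optional initial [rigid_transform()]; identity by default.
#' @param cfg a [rigid_config()].
#' @param verbose print per-level progress.
#' @return The estimated [rigid_transform()], with attributes `trace` (a
#'   tibble of per-level start/end metric values) and `converged`.
#' @export
register_rigid <- function(fixed, moving, init = NULL, cfg = rigid_config(),
                           verbose = FALSE) {
  stopifnot_image(fixed)
  stopifnot_image(moving)
  center <- fixed$origin + (img_dim(fixed) - 1) * fixed$spacing / 2
  if (is.null(init)) init <- rigid_transform(center = center)
  par <- c(init$rotation * cfg$rot_scale, init$translation)
  center <- init$center
  nl <- length(cfg$shrink)
  trace <- vector("list", nl)
  converged <- TRUE

  for (lev in seq_len(nl)) {
    f_l <- downsample_volume(fixed, cfg$shrink[lev])
    m_l <- downsample_volume(moving, cfg$shrink[lev])
    body_l <- new_mask(fill_holes_2d(f_l$voxels > cfg$body_threshold), f_l)
    if (sum(body_l$voxels) == 0L) body_l <- new_mask(array(1L, img_dim(f_l)), f_l)
    pts <- sample_fixed_points(f_l, body_l, cfg$sample_percent[lev],
                               cfg$seed + lev)
    fvals <- f_l$voxels[attr(pts, "voxel_index")]
    frange <- range(fvals)
    mrange <- range(m_l$voxels)
    thr <- usable_threshold(cfg, nrow(pts))
    pc <- sweep(pts, 2L, center, "-")

    eval_at <- function(p, want_grad) {
      rig <- rigid_transform(p[1:3] / cfg$rot_scale, p[4:6], center)
      af <- rigid_affine(rig)
      mapped <- sweep(pts %*% t(af$A), 2L, af$b, "+")
      res <- mattes_mi_core(fvals, mapped, m_l, cfg$n_bins, frange, mrange,
                            want_grad)
      if (res$n_used < thr)
        stop(sprintf(paste0("rigid level %d: only %d of %d samples usable; ",
                            "images may be grossly misaligned"),
                     lev, res$n_used, nrow(pts)), call. = FALSE)
      if (want_grad) {
        g <- chain_rigid_gradient(res$gradient, pts, rig)
        g[1:3] <- g[1:3] / cfg$rot_scale
        list(value = res$value, gradient = g)
      } else list(value = res$value)
    }

    cur <- eval_at(par, TRUE)
    v_start <- cur$value
    step <- cfg$max_step[lev]
    fails <- 0L
    iters <- 0L
    while (iters < cfg$max_iter && step >= cfg$min_step[lev]) {
      gn <- sqrt(sum(cur$gradient^2))
      if (gn == 0) break
      cand <- par - step * cur$gradient / gn
      vc <- eval_at(cand, FALSE)$value
      if (vc < cur$value - 1e-12) {
        par <- cand
        cur <- eval_at(par, TRUE)
        fails <- 0L
      } else {
        step <- step * cfg$relaxation
        fails <- fails + 1L
        if (fails > cfg$max_backtracks) break
      }
      iters <- iters + 1L
    }
    if (fails > cfg$max_backtracks && cur$value > v_start) converged <- FALSE
    trace[[lev]] <- tibble::tibble(level = lev, shrink = cfg$shrink[lev],
                                   n_points = nrow(pts), value_start = v_start,
                                   value_end = cur$value, iterations = iters)
    if (verbose)
      message(sprintf("rigid L%d: -MI %.5f -> %.5f (%d iter, %d pts)",
                      lev, v_start, cur$value, iters, nrow(pts)))
  }
  out <- rigid_transform(par[1:3] / cfg$rot_scale, par[4:6], center)
  attr(out, "trace") <- dplyr::bind_rows(trace)
  attr(out, "converged") <- converged
  if (!converged)
    warning("rigid registration did not improve the metric at every level; ",
            "best-so-far transform returned", call. = FALSE)
  out
}

## ---- elastic stage ------------------------------------------------------

#' Four-level schedule for the elastic stage
#'
#' Per level: Gaussian smoothing kernels (voxels) for the fixed and moving
#' images, the percentage of body voxels sampled by the metric, the
#' L-BFGS-B projected-gradient tolerance, and the control-point grid
#' spacing (mm).  Defaults follow the standard thoracic settings: kernels
#' 16/8/2/0 voxels (with the axial width halved when the axial voxel size
#' is smaller than the in-plane size), sample percentages
#' 0.8/3.4/9.3/19.7%, tolerances 1e-5..1e-8, and grid spacing stepping
#' 96 -> 64 -> 45 -> 30 mm (geometric interpolation between the stated
#' coarsest and finest resolutions).
#'
#' @param fixed,moving the images to be registered (their voxel spacings
#'   select the axial kernel rule).
#' @param grid_spacing per-level control-point spacings (mm), strictly
#'   decreasing.
#' @param sample_percent per-level metric sampling percentages, strictly
#'   increasing.
#' @param tolerance per-level L-BFGS-B projected-gradient tolerances,
#'   strictly decreasing.
#' @return A tibble with one row per level and list-columns
#'   `kernel_fixed`, `kernel_moving`.
#' @export
elastic_schedules <- function(fixed, moving,
                              grid_spacing = c(96, 64, 45, 30),
                              sample_percent = c(0.8, 3.4, 9.3, 19.7),
                              tolerance = c(1e-5, 1e-6, 1e-7, 1e-8)) {
  nl <- length(grid_spacing)
  stopifnot(length(sample_percent) == nl, length(tolerance) == nl)
  if (any(diff(sample_percent) <= 0))
    stop("`sample_percent` must strictly increase with level", call. = FALSE)
  if (any(diff(tolerance) >= 0))
    stop("`tolerance` must strictly decrease with level", call. = FALSE)
  if (any(diff(grid_spacing) >= 0))
    stop("`grid_spacing` must strictly decrease with level", call. = FALSE)
  tibble::tibble(
    level = seq_len(nl),
    kernel_fixed = lapply(seq_len(nl), function(l)
      level_kernel(l, fixed$spacing)),
    kernel_moving = lapply(seq_len(nl), function(l)
      level_kernel(l, moving$spacing)),
    sample_percent = sample_percent,
    tolerance = tolerance,
    grid_spacing = grid_spacing)
}

# axial kernel rule: full axial width when the axial voxel size is at least
# the in-plane size, halved otherwise (never above what the level prescribes)
level_kernel <- function(level, spacing) {
  base <- list(c(16, 16, 16), c(8, 8, 8), c(2, 2, 2), c(0, 0, 0))
  k <- base[[min(level, 4L)]]
  if (spacing[3] < spacing[1] && level <= 2L) k[3] <- k[3] / 2
  k
}

#' Elastic registration configuration
#'
#' @param n_bins,seed,min_samples see [mi_config()].
#' @param max_iter L-BFGS-B iteration cap per level.
#' @param coef_bound box bound (mm) on every B-spline coefficient.
#' @param lmm number of BFGS updates retained.
#' @param min_draw per-level floor on the number of drawn sample points
#'   (capped at the body size), set to the coarsest-level sample count of a
#'   clinical-size run; it keeps absolute sample counts meaningful on small
#'   volumes and is inactive at clinical volume sizes.
#' @return An `elastic_config` list.
#' @export
elastic_config <- function(n_bins = 50L, seed = 2011L, min_samples = 1000L,
                           max_iter = 500L, coef_bound = 60, lmm = 10L,
                           min_draw = 7000L) {
  structure(list(n_bins = as.integer(n_bins), seed = as.integer(seed),
                 min_samples = as.integer(min_samples),
                 max_iter = as.integer(max_iter), coef_bound = coef_bound,
                 lmm = as.integer(lmm), min_draw = as.integer(min_draw)),
            class = "elastic_config")
}

#' Elastic registration by B-spline free-form deformation
#'
#' Starting from the rigid alignment, estimates a cubic B-spline
#' displacement field by minimising negative Mattes mutual information
#' under a four-level multi-resolution schedule: at each level both images
#' are smoothed with the level's Gaussian kernel (multi-resolution is
#' expressed through blur, sampling percentage and grid spacing; the images
#' are never down-sampled), a fresh point set of the level's sampling
#' percentage is drawn, the coefficient lattice is optimised by bounded
#' L-BFGS-B to the level's tolerance, and the lattice is then refined to
#' the next level's spacing.
#'
#' @param fixed,moving pre-processed [image_volume()]s.
#' @param rigid the [rigid_transform()] from [register_rigid()].
#' @param schedules a schedule tibble from [elastic_schedules()]; built
#'   with defaults when `NULL`.
#' @param cfg an [elastic_config()].
#' @param body optional body [new_mask()] on the fixed geometry defining the
#'   sampling domain; derived by thresholding at -400 HU when absent.
#' @param verbose print per-level progress.
#' @return A [composite_transform()] (rigid + fitted B-spline) with
#'   attribute `levels`, a tibble of per-level diagnostics (start/end
#'   metric values, optimiser convergence codes, sample counts).
#' @export
register_elastic <- function(fixed, moving, rigid, schedules = NULL,
                             cfg = elastic_config(), body = NULL,
                             verbose = FALSE) {
  stopifnot_image(fixed)
  stopifnot_image(moving)
  if (!inherits(rigid, "rigid_transform"))
    stop("`rigid` must be a rigid_transform", call. = FALSE)
  if (is.null(schedules)) schedules <- elastic_schedules(fixed, moving)
  if (is.null(body)) body <- new_mask(fill_holes_2d(fixed$voxels > -400), fixed)
  af <- rigid_affine(rigid)
  B <- NULL
  diag_rows <- vector("list", nrow(schedules))
  any_fail <- FALSE

  for (lev in seq_len(nrow(schedules))) {
    sch <- schedules[lev, ]
    # schedule kernels are support widths in voxels; the Gaussian's width
    # parameter (sd) is a quarter of the support (+/- 2 sd)
    f_s <- gaussian_smooth(fixed, sch$kernel_fixed[[1]] / 4)
    m_s <- gaussian_smooth(moving, sch$kernel_moving[[1]] / 4)
    # floor the draw so coarse levels are never starved on small volumes;
    # at clinical volume sizes the percentage always dominates
    n_body <- sum(body$voxels)
    pct <- max(sch$sample_percent, min(100, 100 * cfg$min_draw / n_body))
    pts <- sample_fixed_points(f_s, body, pct, cfg$seed + lev)
    fvals <- f_s$voxels[attr(pts, "voxel_index")]
    frange <- range(fvals)
    mrange <- range(m_s$voxels)
    thr <- usable_threshold(cfg, nrow(pts))
    rigid_part <- sweep(pts %*% t(af$A), 2L, af$b, "+")

    B <- if (is.null(B)) init_bspline_grid(fixed, sch$grid_spacing)
         else refine_bspline_grid(B, sch$grid_spacing)
    gdim <- c(B$grid_size, 3L)

    cache <- new.env(parent = emptyenv())
    evaluate <- function(par) {
      if (!is.null(cache$par) && identical(par, cache$par)) return(cache$res)
      coef <- array(par, gdim)
      D <- cpp_bspline_eval(coef, B$grid_origin, B$grid_spacing, B$grid_size,
                            pts, FALSE)
      res <- mattes_mi_core(fvals, rigid_part + D, m_s, cfg$n_bins,
                            frange, mrange, TRUE)
      if (res$n_used < thr)
        stop(sprintf(paste0("elastic level %d: only %d of %d samples map ",
                            "inside the moving image"),
                     lev, res$n_used, nrow(pts)), call. = FALSE)
      g <- cpp_bspline_scatter(B$grid_origin, B$grid_spacing, B$grid_size,
                               pts, res$gradient)
      cache$par <- par
      cache$res <- list(value = res$value, gradient = as.numeric(g))
      cache$res
    }

    par0 <- as.numeric(B$coefficients)
    v_start <- evaluate(par0)$value
    opt <- optim(par0, fn = function(p) evaluate(p)$value,
                 gr = function(p) evaluate(p)$gradient,
                 method = "L-BFGS-B",
                 lower = -cfg$coef_bound, upper = cfg$coef_bound,
                 control = list(maxit = cfg$max_iter, lmm = cfg$lmm,
                                pgtol = sch$tolerance, factr = 1e3))
    # codes 0/1 are clean; a line-search abort that did not worsen the
    # metric (a kink from samples crossing the moving boundary, or an
    # already-optimal start) is benign
    if (!(opt$convergence %in% c(0L, 1L)) && opt$value > v_start + 1e-12)
      any_fail <- TRUE
    B$coefficients <- array(opt$par, gdim)
    diag_rows[[lev]] <- tibble::tibble(
      level = lev, grid_spacing = sch$grid_spacing, n_points = nrow(pts),
      value_start = v_start, value_end = opt$value,
      convergence = opt$convergence,
      message = if (is.null(opt$message)) "" else opt$message)
    if (verbose)
      message(sprintf("elastic L%d (grid %.0f mm, %d pts): -MI %.5f -> %.5f",
                      lev, sch$grid_spacing, nrow(pts), v_start, opt$value))
  }
  out <- composite_transform(rigid, B)
  attr(out, "levels") <- dplyr::bind_rows(diag_rows)
  if (any_fail)
    warning("L-BFGS-B reported a convergence problem at one or more levels; ",
            "the partial transform is returned (see attr(., 'levels'))",
            call. = FALSE)
  out
}
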