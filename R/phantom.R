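#' Synthetic thorax phantom specification
#'
#' Describes a piecewise-constant thorax: an ellipsoidal body of soft
#' tissue containing two ellipsoidal lungs, a vertebral bone column, a
#' basal pleural-effusion layer in the left lung, band-limited intensity
#' texture, a treatment-couch slab behind the patient, and a catalog of
#' anatomical landmarks rendered as small high-contrast spheres.  The
#' default grid matches a thoracic planning kVCT (192 x 192 x 60 voxels at
#' 0.976 x 0.976 x 3.27 mm).
#'
#' Patient orientation: x increases towards the patient's left, y towards
#' posterior (the couch sits at high y), z towards the head.
#'
#' @param dims grid size (voxels).
#' @param spacing voxel size (mm).
#' @param body_semiaxes,lung_semiaxes ellipsoid semi-axes (mm).
#' @param lung_offset center of the left lung relative to the body center
#'   (mm); the right lung mirrors it in x.
#' @param bone_radius,bone_offset_y vertebral column cylinder radius and
#'   posterior offset (mm).
#' @param tissue named HU values for air, lung, soft tissue, bone and
#'   pleural effusion.
#' @param effusion_level_frac the basal fraction of the left lung's z
#'   semi-axis filled by effusion at baseline (the effusion occupies
#'   `z < z_lung - effusion_level_frac * semi_z`); 0 disables it.
#' @param texture_amplitude standard deviation (HU) of the band-limited
#'   texture added inside the body (default 80 HU, the scale of vascular
#'   and parenchymal structure that makes tissue interiors informative for
#'   a 50-bin mutual-information metric); 0 gives a strictly
#'   piecewise-constant phantom.  Values are clamped at -1000 HU, the
#'   physical floor of the scale.
#' @param texture_sigma smoothing width (voxels) of the texture field.
#' @param landmark_radius_voxels radius of the rendered landmark spheres,
#'   in in-plane voxels.
#' @param couch include the detached couch slab.
#' @param seed RNG seed for the texture field.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dims = c(192, 192, 60),
                         spacing = c(0.976, 0.976, 3.27),
                         body_semiaxes = c(80, 62, 140),
                         lung_semiaxes = c(26, 40, 70),
                         lung_offset = c(36, -4, 0),
                         bone_radius = 12,
                         bone_offset_y = 40,
                         tissue = c(air = -1000, lung = -850, soft = 0,
                                    bone = 700, effusion = 20),
                         effusion_level_frac = 0.5,
                         texture_amplitude = 80,
                         texture_sigma = 2,
                         landmark_radius_voxels = 3,
                         couch = TRUE,
                         seed = 1L) {
  spec <- structure(list(dims = as.integer(dims), spacing = as.numeric(spacing),
                         body_semiaxes = body_semiaxes,
                         lung_semiaxes = lung_semiaxes,
                         lung_offset = lung_offset,
                         bone_radius = bone_radius,
                         bone_offset_y = bone_offset_y,
                         tissue = tissue,
                         effusion_level_frac = effusion_level_frac,
                         texture_amplitude = texture_amplitude,
                         texture_sigma = texture_sigma,
                         landmark_radius_voxels = landmark_radius_voxels,
                         couch = isTRUE(couch),
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

phantom_center <- function(spec) (spec$dims - 1) * spec$spacing / 2

validate_phantom_spec <- function(spec) {
  if (any(spec$dims < 16L))
    stop("phantom grid must be at least 16 voxels per axis", call. = FALSE)
  if (any(spec$spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  # lungs strictly inside the body: probe directions on the unit sphere
  th <- seq(0, pi, length.out = 13)
  ph <- seq(0, 2 * pi, length.out = 25)
  u <- cbind(c(outer(sin(th), cos(ph))), c(outer(sin(th), sin(ph))),
             rep(cos(th), times = length(ph)))
  for (sgn in c(1, -1)) {
    ctr <- spec$lung_offset * c(sgn, 1, 1)
    surf <- sweep(u %*% diag(spec$lung_semiaxes), 2, ctr, "+")
    rho <- sqrt(rowSums(sweep(surf, 2, spec$body_semiaxes, "/")^2))
    if (any(rho >= 1))
      stop("lungs must lie strictly inside the body ellipsoid", call. = FALSE)
  }
  lm <- phantom_landmark_catalog(spec)
  rho <- sqrt(rowSums(sweep(as.matrix(lm[, c("dx", "dy", "dz")]), 2,
                            spec$body_semiaxes, "/")^2))
  if (any(rho >= 1))
    stop("all landmarks must lie inside the body", call. = FALSE)
  invisible(spec)
}

# landmark catalog: offsets (mm) relative to the body center
phantom_landmark_catalog <- function(spec) {
  lo <- spec$lung_offset
  by <- spec$bone_offset_y
  tibble::tibble(
    label = c("carina", "bronchial_bifurcation_left",
              "bronchial_bifurcation_right", "vertebral_body_sup",
              "vertebral_body_inf", "aortic_arch", "lung_apex_left",
              "lung_apex_right", "breast_bone", "rib_left", "rib_right"),
    dx = c(0, 20, -20, 0, 0, 8, lo[1], -lo[1], 0, 55, -55),
    dy = c(-4, -4, -4, by, by, -14, lo[2], lo[2], -52, -25, -25),
    dz = c(25, 12, 12, 45, -45, 40, 0.85 * spec$lung_semiaxes[3],
           0.85 * spec$lung_semiaxes[3], 10, -10, -10))
}

## ---- analytic anatomy ---------------------------------------------------

# elliptical radius of points `p` (n x 3) about center `c` with semi-axes `s`
ell_rho <- function(p, ctr, semi) {
  sqrt(((p[, 1] - ctr[1]) / semi[1])^2 +
       ((p[, 2] - ctr[2]) / semi[2])^2 +
       ((p[, 3] - ctr[3]) / semi[3])^2)
}

phantom_membership <- function(spec, p) {
  ctr <- phantom_center(spec)
  in_body <- ell_rho(p, ctr, spec$body_semiaxes) < 1
  cl <- ctr + spec$lung_offset
  cr <- ctr + spec$lung_offset * c(-1, 1, 1)
  in_cav_l <- ell_rho(p, cl, spec$lung_semiaxes) < 1
  in_cav_r <- ell_rho(p, cr, spec$lung_semiaxes) < 1
  z_eff <- cl[3] - spec$effusion_level_frac * spec$lung_semiaxes[3]
  in_eff <- if (spec$effusion_level_frac > 0)
    in_cav_l & p[, 3] < z_eff else rep(FALSE, nrow(p))
  in_bone <- in_body &
    (((p[, 1] - ctr[1]) / spec$bone_radius)^2 +
     ((p[, 2] - (ctr[2] + spec$bone_offset_y)) / spec$bone_radius)^2) < 1
  list(body = in_body, cavity_left = in_cav_l, cavity_right = in_cav_r,
       effusion = in_eff, bone = in_bone,
       lung_left = in_cav_l & !in_eff, lung_right = in_cav_r)
}

#' Generate a synthetic thorax kVCT with ground truth
#'
#' Builds the phantom volume described by a [phantom_spec()] and the
#' matching ground truth: the landmark catalog (analytic centers, in both
#' frames — identical at generation time), the true left/right lung masks,
#' and an identity deformation.  Landmarks are rendered as 3-voxel-radius
#' +300 HU spheres so they are detectable in both modalities; ground-truth
#' residuals always use the analytic centers, never re-detected positions.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `image` (an [image_volume()], modality kVCT) and
#'   `truth` (a `ground_truth` object).
#' @export
generate_thorax_phantom <- function(spec = phantom_spec()) {
  validate_phantom_spec(spec)
  img0 <- image_volume(array(0, spec$dims), spec$spacing,
                       modality = "kVCT")
  p <- voxel_centers(img0)
  mem <- phantom_membership(spec, p)
  hu <- rep(spec$tissue[["air"]], nrow(p))
  hu[mem$body] <- spec$tissue[["soft"]]
  hu[mem$lung_left | mem$lung_right] <- spec$tissue[["lung"]]
  hu[mem$effusion] <- spec$tissue[["effusion"]]
  hu[mem$bone] <- spec$tissue[["bone"]]

  tex <- numeric(nrow(p))
  if (spec$texture_amplitude > 0) {
    raw <- with_seed(spec$seed, rnorm(nrow(p)))
    raw <- array(raw, spec$dims)
    sm <- cpp_gauss_smooth(raw, spec$dims, rep(spec$texture_sigma, 3))
    tex <- as.numeric(sm) / sd(sm) * spec$texture_amplitude
    hu[mem$body] <- hu[mem$body] + tex[mem$body]
  }

  if (spec$couch) {
    d <- spec$dims
    ext <- d * spec$spacing
    in_couch <- p[, 1] > 0.2 * ext[1] & p[, 1] < 0.8 * ext[1] &
      p[, 2] > 0.90 * ext[2] & p[, 2] < 0.95 * ext[2]
    hu[in_couch] <- spec$tissue[["bone"]]
  }

  ctr <- phantom_center(spec)
  cat_lm <- phantom_landmark_catalog(spec)
  lm_pos <- sweep(as.matrix(cat_lm[, c("dx", "dy", "dz")]), 2, ctr, "+")
  r_lm <- spec$landmark_radius_voxels * spec$spacing[1]
  for (i in seq_len(nrow(lm_pos))) {
    d2 <- (p[, 1] - lm_pos[i, 1])^2 + (p[, 2] - lm_pos[i, 2])^2 +
      (p[, 3] - lm_pos[i, 3])^2
    hu[d2 < r_lm^2] <- 300
  }

  hu <- pmax(hu, -1000)  # air is the physical floor of the HU scale
  img <- image_volume(array(hu, spec$dims), spec$spacing, modality = "kVCT")
  marks <- landmark_set(cat_lm$label, lm_pos[, 1], lm_pos[, 2], lm_pos[, 3],
                        frame = "kVCT")
  marks_def <- landmark_set(cat_lm$label, lm_pos[, 1], lm_pos[, 2],
                            lm_pos[, 3], frame = "MVCT")
  lungs_fixed <- list(
    left = new_mask(array(mem$lung_left, spec$dims), img),
    right = new_mask(array(mem$lung_right, spec$dims), img))
  truth <- structure(list(
    spec = spec,
    landmarks = marks,
    landmarks_deformed = marks_def,
    lungs_fixed = lungs_fixed,
    lungs_deformed = lungs_fixed,
    forward_field = NULL,
    deformation = NULL,
    texture = tex), class = "ground_truth")
  list(image = img, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d landmarks; deformation: %s\n",
              nrow(x$landmarks),
              if (is.null(x$deformation)) "identity" else x$deformation$mode))
  invisible(x)
}

#' Synthetic deformation specification
#'
#' The anatomical-change taxonomy emulated by the phantom: mediastinal
#' shift, progressing atelectasis of the left lung, resolving basal
#' pleural effusion, whole-body shrink (weight loss), or a generic smooth
#' random field.  Fields are sums of compactly supported smooth bumps
#' multiplied by an image-boundary taper, so displacement is exactly zero
#' at the image boundary.
#'
#' @param mode one of `"mediastinal_shift"`, `"atelectasis"`,
#'   `"pleural_effusion"`, `"body_shrink"`, `"smooth_random"`.
#' @param amplitude peak displacement in mm, except for `"atelectasis"`
#'   where it is the target percent volume loss of the left lung.
#' @param seed RNG seed (used by `"smooth_random"` and the background
#'   field).
#' @param n_bumps number of random bumps for `"smooth_random"`.
#' @param background_amplitude peak displacement (mm) of a distributed
#'   smooth random field superimposed on the mode-specific change,
#'   emulating the posture and free-breathing differences that accompany
#'   any repeat acquisition; 0 (the default) disables it.
#' @return A `deformation_spec` list.
#' @export
deformation_spec <- function(mode = c("mediastinal_shift", "atelectasis",
                                      "pleural_effusion", "body_shrink",
                                      "smooth_random"),
                             amplitude = NULL, seed = 1L, n_bumps = 6L,
                             background_amplitude = 0) {
  mode <- match.arg(mode)
  if (is.null(amplitude))
    amplitude <- switch(mode, mediastinal_shift = 8, atelectasis = 25,
                        pleural_effusion = 8, body_shrink = 6,
                        smooth_random = 8)
  structure(list(mode = mode, amplitude = amplitude, seed = as.integer(seed),
                 n_bumps = as.integer(n_bumps),
                 background_amplitude = background_amplitude),
            class = "deformation_spec")
}

# C2 compact bump: (1 - rho^2)^3 on rho < 1
bump <- function(rho) ifelse(rho < 1, (1 - rho^2)^3, 0)

smoothstep01 <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * x * (x * (x * 6 - 15) + 10)
}

# taper to zero within `width` mm of the image boundary
boundary_taper <- function(spec, p, width = 12) {
  ext <- spec$dims * spec$spacing
  d <- pmin(p[, 1], ext[1] - p[, 1], p[, 2], ext[2] - p[, 2],
            p[, 3], ext[3] - p[, 3])
  smoothstep01(d / width)
}

# forward displacement function u(p) for a deformation spec; returns n x 3
deformation_field_fun <- function(spec, d) {
  mode_fun <- deformation_mode_fun(spec, d)
  bg <- d$background_amplitude
  if (is.null(bg) || bg == 0) return(mode_fun)
  bg_fun <- deformation_mode_fun(
    spec, deformation_spec("smooth_random", amplitude = bg,
                           seed = d$seed + 1000L, n_bumps = d$n_bumps))
  function(p) mode_fun(p) + bg_fun(p)
}

deformation_mode_fun <- function(spec, d) {
  ctr <- phantom_center(spec)
  force(d)
  switch(d$mode,
    mediastinal_shift = function(p) {
      rho <- ell_rho(p, ctr + c(0, -4, 0), c(55, 50, 85))
      u <- cbind(d$amplitude * bump(rho), 0, 0)
      u * boundary_taper(spec, p)
    },
    atelectasis = function(p) {
      k <- (1 - d$amplitude / 100)^(1 / 3)
      cl <- ctr + spec$lung_offset
      rho <- ell_rho(p, cl, 1.5 * spec$lung_semiaxes)
      g <- 1 - smoothstep01((rho - 2 / 3) * 3)
      u <- (k - 1) * g * sweep(p, 2, cl, "-")
      u * boundary_taper(spec, p)
    },
    pleural_effusion = function(p) {
      cl <- ctr + spec$lung_offset
      z_eff <- cl[3] - spec$effusion_level_frac * spec$lung_semiaxes[3]
      rho <- ell_rho(p, c(cl[1], cl[2], z_eff),
                     c(1.2 * spec$lung_semiaxes[1],
                       1.2 * spec$lung_semiaxes[2], 30))
      u <- cbind(0, 0, -d$amplitude * bump(rho))
      u * boundary_taper(spec, p)
    },
    body_shrink = function(p) {
      # shell half-width 0.5 in normalised radius keeps the field resolvable
      # by the finest (30 mm) control-point grid
      rho <- ell_rho(p, ctr, spec$body_semiaxes)
      w <- bump(abs(rho - 1) / 0.5)
      dp <- sweep(p, 2, ctr, "-")
      nrm <- sqrt(rowSums(dp^2)) + 1e-9
      u <- -d$amplitude * w * dp / nrm
      u * boundary_taper(spec, p)
    },
    smooth_random = {
      pars <- with_seed(d$seed, {
        lapply(seq_len(d$n_bumps), function(i) {
          list(ctr = ctr + (runif(3) - 0.5) * spec$body_semiaxes,
               radius = runif(1, 35, 65),
               dir = { v <- rnorm(3); v / sqrt(sum(v^2)) })
        })
      })
      raw <- function(p) {
        u <- matrix(0, nrow(p), 3)
        for (b in pars) {
          rho <- sqrt(rowSums(sweep(p, 2, b$ctr, "-")^2)) / b$radius
          u <- u + outer(bump(rho), b$dir)
        }
        u
      }
      # normalise once on a fixed probe lattice so the field definition does
      # not depend on where it is later evaluated
      ext <- spec$dims * spec$spacing
      probe <- as.matrix(expand.grid(seq(0, ext[1], length.out = 25),
                                     seq(0, ext[2], length.out = 25),
                                     seq(0, ext[3], length.out = 25)))
      mx <- max(sqrt(rowSums(raw(probe)^2)))
      scale <- if (mx > 0) d$amplitude / mx else 0
      function(p) raw(p) * scale * boundary_taper(spec, p)
    })
}

# minimum Jacobian determinant of a forward field on the grid
field_min_jacobian <- function(field, spacing) {
  d <- dim(field)[1:3]
  J <- array(0, c(d, 3, 3))
  for (comp in 1:3) {
    for (ax in 1:3) {
      u <- field[, , , comp]
      sh <- function(off) {
        idx <- pmin(pmax(seq_len(d[ax]) + off, 1L), d[ax])
        switch(ax, u[idx, , , drop = FALSE], u[, idx, , drop = FALSE],
               u[, , idx, drop = FALSE])
      }
      J[, , , comp, ax] <- (sh(1L) - sh(-1L)) / (2 * spacing[ax])
    }
  }
  det <- (1 + J[, , , 1, 1]) * ((1 + J[, , , 2, 2]) * (1 + J[, , , 3, 3]) -
                                J[, , , 2, 3] * J[, , , 3, 2]) -
    J[, , , 1, 2] * (J[, , , 2, 1] * (1 + J[, , , 3, 3]) -
                     J[, , , 2, 3] * J[, , , 3, 1]) +
    J[, , , 1, 3] * (J[, , , 2, 1] * J[, , , 3, 2] -
                     (1 + J[, , , 2, 2]) * J[, , , 3, 1])
  min(det)
}

#' Apply a known smooth deformation to a phantom
#'
#' Warps the phantom by the forward map `T(p) = p + u(p)` of a
#' [deformation_spec()] (the image is synthesised by numerically inverting
#' the map per voxel, which converges because the fields are smooth
#' contractions) and updates the ground truth consistently: advected
#' landmarks, the dense forward field, and the true lung masks of the
#' deformed frame.  For `"pleural_effusion"` the basal effusion layer is
#' additionally re-aerated (its HU restored to lung tissue), modelling a
#' resolved effusion.
#'
#' @param img the phantom [image_volume()] from [generate_thorax_phantom()].
#' @param truth its `ground_truth`.
#' @param d a [deformation_spec()].
#' @return A list with the deformed `image` and updated `truth`.
#' @export
apply_synthetic_deformation <- function(img, truth, d) {
  stopifnot_image(img)
  spec <- truth$spec
  u_fun <- deformation_field_fun(spec, d)
  q <- voxel_centers(img)

  if (d$amplitude == 0 &&
      (is.null(d$background_amplitude) || d$background_amplitude == 0)) {
    out_truth <- truth
    out_truth$deformation <- d
    out_truth$forward_field <- NULL
    return(list(image = img, truth = out_truth))
  }

  # fixed-point inversion of p + u(p) = q
  p_est <- q
  for (it in 1:30) p_est <- q - u_fun(p_est)

  src <- img
  mem_fun <- function(pp) phantom_membership(spec, pp)
  if (d$mode == "pleural_effusion") {
    mem0 <- mem_fun(voxel_centers(img))
    v <- as.numeric(src$voxels)
    v[mem0$effusion] <- spec$tissue[["lung"]] + truth$texture[mem0$effusion]
    src <- image_volume(array(v, img_dim(img)), img$spacing, img$origin,
                        img$modality)
  }
  warped <- cpp_trilinear(src$voxels, img_dim(src), src$spacing, src$origin,
                          p_est, spec$tissue[["air"]], FALSE)$values
  def_img <- image_volume(array(warped, img_dim(img)), img$spacing,
                          img$origin, "synthetic")

  field <- array(u_fun(q), c(img_dim(img), 3L))
  mj <- field_min_jacobian(field, img$spacing)
  if (mj <= 0)
    stop(sprintf("foldover detected: minimum Jacobian determinant %.3f", mj),
         call. = FALSE)

  lm <- landmark_matrix(truth$landmarks)
  lm_def <- lm + u_fun(lm)
  marks_def <- landmark_set(truth$landmarks$label, lm_def[, 1], lm_def[, 2],
                            lm_def[, 3], frame = "MVCT")

  mem_back <- mem_fun(p_est)
  aer_left <- if (d$mode == "pleural_effusion") mem_back$cavity_left
              else mem_back$lung_left
  lungs_def <- list(
    left = new_mask(array(aer_left, img_dim(img)), def_img),
    right = new_mask(array(mem_back$lung_right, img_dim(img)), def_img))

  out_truth <- truth
  out_truth$landmarks_deformed <- marks_def
  out_truth$lungs_deformed <- lungs_def
  out_truth$forward_field <- field
  out_truth$deformation <- d
  list(image = def_img, truth = out_truth)
}

#' Degrade a phantom to MVCT-like quality
#'
#' Resamples to MVCT voxel spacing, restricts the axial field of view,
#' applies a mild linear HU contrast scaling about air, and adds Gaussian
#' noise — emulating the lower image quality and restricted acquisition
#' extent of daily megavoltage CT.
#'
#' @param img an [image_volume()].
#' @param spacing MVCT voxel size (mm); default 0.754 x 0.754 x 4.
#' @param fov_z physical z interval `(lo, hi)` to retain; full extent when
#'   `NULL`.
#' @param noise_sd additive Gaussian noise standard deviation (HU).
#' @param contrast_scale linear contrast factor about air
#'   (`out = -1000 + scale * (in + 1000)`).
#' @param seed RNG seed for the noise.
#' @return The degraded [image_volume()] (modality MVCT).
#' @export
degrade_to_mvct <- function(img, spacing = c(0.754, 0.754, 4), fov_z = NULL,
                            noise_sd = 30, contrast_scale = 0.9, seed = 1L) {
  stopifnot_image(img)
  spacing <- rep_len(as.numeric(spacing), 3L)
  ext <- physical_extent(img, 3L)
  if (is.null(fov_z)) fov_z <- ext
  if (fov_z[1] < ext[1] - 1e-9 || fov_z[2] > ext[2] + 1e-9 ||
      fov_z[2] <= fov_z[1])
    stop("`fov_z` must be a nonempty interval inside the image z extent",
         call. = FALSE)
  d <- img_dim(img)
  nxy <- floor((d[1:2] - 1) * img$spacing[1:2] / spacing[1:2]) + 1
  nz <- max(1L, floor((fov_z[2] - fov_z[1]) / spacing[3]))
  org <- c(img$origin[1:2], fov_z[1] + spacing[3] / 2)
  ref <- image_volume(array(0, c(nxy, nz)), spacing, org, "MVCT")
  out <- resample_to_reference(img, rigid_transform(), ref)
  v <- -1000 + contrast_scale * (out$voxels + 1000)
  if (noise_sd > 0)
    v <- v + array(with_seed(seed, rnorm(length(v), 0, noise_sd)), dim(v))
  image_volume(v, spacing, org, "MVCT")
}

#' Ground-truth registration error at phantom landmarks
#'
#' Phantom analogue of the landmark target registration error, with the
#' ground-truth mapped positions standing in for expert detection:
#' `|T_est(p) - T_truth(p)|` per landmark.
#'
#' @param estimated the estimated [composite_transform()] (or rigid).
#' @param truth a `ground_truth`.
#' @param labels landmark labels to evaluate (all by default); unknown
#'   labels raise an error.
#' @return A `tre` summary (see [target_registration_error()]).
#' @export
ground_truth_error <- function(estimated, truth, labels = NULL) {
  if (is.null(labels)) labels <- truth$landmarks$label
  unknown <- setdiff(labels, truth$landmarks$label)
  if (length(unknown) > 0L)
    stop(sprintf("unknown landmark label(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  sub <- truth$landmarks[match(labels, truth$landmarks$label), ]
  est <- transform_landmarks(sub, estimated)
  ref <- truth$landmarks_deformed
  target_registration_error(est, ref)
}
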