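test_that("phantom generation is seed-deterministic with plausible anatomy", {
  spec <- test_phantom_spec(seed = 8)
  a <- generate_thorax_phantom(spec)
  b <- generate_thorax_phantom(spec)
  expect_identical(a$image$voxels, b$image$voxels)
  # lung voxel fraction of the body within the anatomical range
  body <- extract_body_mask(a$image)
  lung_frac <- sum(a$truth$lungs_fixed$left$voxels +
                     a$truth$lungs_fixed$right$voxels) / sum(body$voxels)
  expect_gt(lung_frac, 0.05)
  expect_lt(lung_frac, 0.40)
  # landmarks sit inside the body
  lm <- landmark_matrix(a$truth$landmarks)
  li <- round(sweep(lm, 2, a$image$origin, "-") %*%
                diag(1 / a$image$spacing)) + 1
  for (i in seq_len(nrow(li)))
    expect_equal(body$voxels[li[i, 1], li[i, 2], li[i, 3]], 1L)
})

test_that("zero texture gives a strictly piecewise-constant phantom", {
  spec <- test_phantom_spec(texture_amplitude = 0)
  ph <- generate_thorax_phantom(spec)
  # outside landmark spheres: exactly the five tissue values
  lm <- landmark_matrix(ph$truth$landmarks)
  p <- voxel_centers(ph$image)
  near_lm <- rep(FALSE, nrow(p))
  r <- spec$landmark_radius_voxels * spec$spacing[1] + 1
  for (i in seq_len(nrow(lm)))
    near_lm <- near_lm | (rowSums(sweep(p, 2, lm[i, ], "-")^2) < r^2)
  vals <- unique(as.numeric(ph$image$voxels)[!near_lm])
  expect_setequal(vals, unname(spec$tissue))
  expect_length(vals, 5)
})

test_that("stored truth masks agree with the segmentation pathway", {
  ph <- preprocessed_test_phantom()
  seg <- segment_lungs_region_growing(ph$image, body = ph$body)
  lr <- split_left_right(seg, ph$body)
  expect_gte(jaccard_index(lr$left, ph$truth$lungs_fixed$left), 0.97)
  expect_gte(jaccard_index(lr$right, ph$truth$lungs_fixed$right), 0.97)
})

test_that("zero-amplitude deformation changes nothing", {
  ph <- generate_thorax_phantom(test_phantom_spec())
  d <- deformation_spec("mediastinal_shift", amplitude = 0)
  out <- apply_synthetic_deformation(ph$image, ph$truth, d)
  expect_identical(out$image$voxels, ph$image$voxels)
  expect_equal(landmark_matrix(out$truth$landmarks_deformed),
               landmark_matrix(ph$truth$landmarks_deformed))
})

test_that("atelectasis shrinks the left lung by the requested fraction", {
  ph <- generate_thorax_phantom(test_phantom_spec())
  out <- apply_synthetic_deformation(ph$image, ph$truth,
                                     deformation_spec("atelectasis",
                                                      amplitude = 25))
  ratio <- sum(out$truth$lungs_deformed$left$voxels) /
    sum(ph$truth$lungs_fixed$left$voxels)
  expect_equal(ratio, 0.75, tolerance = 0.03 / 0.75)
  # right lung essentially untouched
  ratio_r <- sum(out$truth$lungs_deformed$right$voxels) /
    sum(ph$truth$lungs_fixed$right$voxels)
  expect_equal(ratio_r, 1, tolerance = 0.02)
})

test_that("deformed landmarks equal the field evaluated at the landmarks", {
  ph <- generate_thorax_phantom(test_phantom_spec())
  for (mode in c("mediastinal_shift", "atelectasis", "pleural_effusion",
                 "body_shrink", "smooth_random")) {
    out <- apply_synthetic_deformation(ph$image, ph$truth,
                                       deformation_spec(mode, seed = 6))
    lm <- landmark_matrix(ph$truth$landmarks)
    lm_def <- landmark_matrix(out$truth$landmarks_deformed)
    # advected landmark = analytic field evaluated at the landmark
    u_fun <- mvctreg:::deformation_field_fun(ph$truth$spec,
                                             out$truth$deformation)
    expect_lt(max(abs(lm + u_fun(lm) - lm_def)), 1e-6)
    # the stored dense field is that same field on the voxel grid
    fld <- out$truth$forward_field
    p <- voxel_centers(ph$image)
    sel <- seq(1, nrow(p), length.out = 200)
    flat <- matrix(fld, ncol = 3)
    expect_lt(max(abs(flat[sel, ] - u_fun(p[sel, , drop = FALSE]))), 1e-9)
    # fields are invertible at generated amplitudes
    expect_gt(field_min_jacobian_helper(fld, ph$image$spacing), 0)
  }
})

test_that("pleural effusion resolution re-aerates the basal lung", {
  ph <- generate_thorax_phantom(test_phantom_spec())
  base_left <- sum(ph$truth$lungs_fixed$left$voxels)
  out <- apply_synthetic_deformation(ph$image, ph$truth,
                                     deformation_spec("pleural_effusion"))
  def_left <- sum(out$truth$lungs_deformed$left$voxels)
  expect_gt(def_left, base_left * 1.05)
  # the re-aerated voxels read as lung tissue in the image
  seg <- segment_lungs_region_growing(out$image,
                                      body = extract_body_mask(out$image))
  lr <- split_left_right(seg)
  expect_gte(jaccard_index(lr$left, out$truth$lungs_deformed$left), 0.95)
})

test_that("MVCT degradation follows its geometry and noise contract", {
  ph <- generate_thorax_phantom(test_phantom_spec())
  img <- ph$image
  # identity settings reproduce the image exactly
  same <- degrade_to_mvct(img, spacing = img$spacing, noise_sd = 0,
                          contrast_scale = 1, seed = 2)
  expect_equal(same$voxels, img$voxels, tolerance = 1e-12)
  # slice count at 4 mm spacing
  mv <- degrade_to_mvct(img, spacing = c(2.5, 2.5, 4), noise_sd = 0,
                        contrast_scale = 1, seed = 2)
  ext <- diff(physical_extent(img, 3))
  expect_lte(abs(img_dim(mv)[3] - floor(ext / 4)), 1)
  expect_equal(mv$modality, "MVCT")
  # noise calibration: sample SD of (noisy - clean) near the nominal SD
  noisy <- degrade_to_mvct(img, spacing = img$spacing, noise_sd = 30,
                           contrast_scale = 1, seed = 2)
  s <- sd(noisy$voxels - img$voxels)
  expect_gt(s, 27)
  expect_lt(s, 33)
  # determinism
  noisy2 <- degrade_to_mvct(img, spacing = img$spacing, noise_sd = 30,
                            contrast_scale = 1, seed = 2)
  expect_identical(noisy$voxels, noisy2$voxels)
  expect_error(degrade_to_mvct(img, fov_z = c(-100, 1000)), "fov_z")
})

test_that("ground-truth error reports constructed offsets", {
  ph <- generate_thorax_phantom(test_phantom_spec())
  out <- apply_synthetic_deformation(ph$image, ph$truth,
                                     deformation_spec("mediastinal_shift",
                                                      amplitude = 6))
  # identity transform on a 10 mm-shifted phantom: mean residual = 10
  shifted <- ph$truth
  lm <- landmark_matrix(shifted$landmarks)
  shifted$landmarks_deformed <- landmark_set(
    shifted$landmarks$label, lm[, 1] + 10, lm[, 2], lm[, 3], frame = "MVCT")
  gt <- ground_truth_error(rigid_transform(), shifted)
  expect_equal(gt$mean, 10, tolerance = 1e-12)
  # a transform equal to the truth map has (near) zero residual: emulate by
  # translating only, on a pure-translation truth
  gt2 <- ground_truth_error(rigid_transform(translation = c(10, 0, 0)),
                            shifted)
  expect_lt(gt2$max, 1e-9)
  expect_error(ground_truth_error(rigid_transform(), out$truth,
                                  labels = "nonexistent"), "unknown")
})
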