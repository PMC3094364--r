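# registration recovery on the noise-free phantom; runtimes are kept small
# by the test phantom's 64 x 64 x 32 grid

test_that("self-registration stays at the identity", {
  ph <- preprocessed_test_phantom()
  mv <- ph$image
  mv$modality <- "MVCT"
  rig <- register_rigid(ph$image, mv)
  expect_lt(max(abs(rig$translation)), 0.2)
  expect_lt(max(abs(rig$rotation)) * 180 / pi, 0.2)
})

test_that("known translations are recovered within half a voxel", {
  ph <- preprocessed_test_phantom()
  t_true <- c(6, -4, 4)
  mv <- shifted_pair(ph$image, rigid_transform(translation = t_true))
  rig <- register_rigid(ph$image, mv)
  err <- abs(rig$translation - t_true) / ph$image$spacing
  expect_lt(max(err), 0.5)
  expect_lt(max(abs(rig$rotation)) * 180 / pi, 0.5)
  # the per-level metric never ends above its start
  tr <- attr(rig, "trace")
  expect_true(all(tr$value_end <= tr$value_start + 1e-12))
})

test_that("known rotations are recovered within half a degree", {
  ph <- preprocessed_test_phantom()
  ctr <- ph$image$origin + (img_dim(ph$image) - 1) * ph$image$spacing / 2
  rot_true <- c(0, 0, 5 * pi / 180)
  mv <- shifted_pair(ph$image, rigid_transform(rot_true, center = ctr))
  rig <- register_rigid(ph$image, mv)
  expect_lt(max(abs(rig$rotation - rot_true)) * 180 / pi, 0.5)
})

test_that("rigid registration is deterministic given the seed", {
  ph <- preprocessed_test_phantom()
  mv <- shifted_pair(ph$image, rigid_transform(translation = c(3, 2, -4)))
  a <- register_rigid(ph$image, mv)
  b <- register_rigid(ph$image, mv)
  expect_identical(a$translation, b$translation)
  expect_identical(a$rotation, b$rotation)
})

test_that("elastic schedule defaults follow the level rules", {
  fx <- image_volume(array(0, c(20, 20, 20)), c(1, 1, 4))
  mv <- image_volume(array(0, c(20, 20, 20)), c(0.754, 0.754, 4))
  sch <- elastic_schedules(fx, mv)
  expect_equal(sch$sample_percent, c(0.8, 3.4, 9.3, 19.7))
  expect_equal(sch$tolerance, c(1e-5, 1e-6, 1e-7, 1e-8))
  expect_equal(sch$grid_spacing, c(96, 64, 45, 30))
  # z spacing >= x spacing: full axial kernels
  expect_equal(sch$kernel_fixed[[1]], c(16, 16, 16))
  expect_equal(sch$kernel_fixed[[2]], c(8, 8, 8))
  # z spacing < x spacing: halved axial kernel at the coarse levels
  fx2 <- image_volume(array(0, c(20, 20, 20)), c(2, 2, 1))
  sch2 <- elastic_schedules(fx2, mv)
  expect_equal(sch2$kernel_fixed[[1]], c(16, 16, 8))
  expect_equal(sch2$kernel_fixed[[2]], c(8, 8, 4))
  expect_equal(sch2$kernel_fixed[[3]], c(2, 2, 2))
  # invariants on the level progressions
  expect_error(elastic_schedules(fx, mv, sample_percent = c(5, 4, 9, 20)),
               "increase")
  expect_error(elastic_schedules(fx, mv, tolerance = c(1e-5, 1e-5, 1e-7, 1e-8)),
               "decrease")
  expect_error(elastic_schedules(fx, mv, grid_spacing = c(96, 96, 45, 30)),
               "decrease")
})

test_that("null deformation keeps the elastic field near zero", {
  ph <- preprocessed_test_phantom()
  mv <- ph$image
  mv$modality <- "MVCT"
  rig <- register_rigid(ph$image, mv)
  ela <- register_elastic(ph$image, mv, rig, body = ph$body)
  fld <- dense_displacement_field(ela, ph$image) -
    dense_displacement_field(rig, ph$image)
  mag <- sqrt(apply(fld^2, 1:3, sum))
  # the field is constrained by data only where samples live: inside the body
  mx <- max(mag[ph$body$voxels == 1])
  expect_lt(mx, 0.5 * max(ph$image$spacing))
  # per-level descent
  lv <- attr(ela, "levels")
  expect_true(all(lv$value_end <= lv$value_start + 1e-12))
})

test_that("a known smooth deformation is recovered below voxel size", {
  ph <- generate_thorax_phantom(test_phantom_spec())
  def <- apply_synthetic_deformation(ph$image, ph$truth,
                                     deformation_spec("smooth_random",
                                                      amplitude = 10,
                                                      seed = 2))
  body <- extract_body_mask(ph$image)
  fx <- mask_background(ph$image, body)
  mv <- def$image
  mv$modality <- "MVCT"
  rig <- register_rigid(fx, mv)
  ela <- register_elastic(fx, mv, rig, body = body)
  gt_r <- ground_truth_error(composite_transform(rig), def$truth)
  gt_e <- ground_truth_error(ela, def$truth)
  expect_lt(gt_e$mean, max(ph$image$spacing))
  expect_lt(gt_e$mean, gt_r$mean)
})

test_that("elastic registration is deterministic given the seed", {
  ph <- generate_thorax_phantom(test_phantom_spec())
  def <- apply_synthetic_deformation(ph$image, ph$truth,
                                     deformation_spec("mediastinal_shift"))
  body <- extract_body_mask(ph$image)
  fx <- mask_background(ph$image, body)
  mv <- def$image
  mv$modality <- "MVCT"
  rig <- register_rigid(fx, mv)
  a <- register_elastic(fx, mv, rig, body = body)
  b <- register_elastic(fx, mv, rig, body = body)
  expect_identical(a$bspline$coefficients, b$bspline$coefficients)
})
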