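test_that("rigid transforms compose with their inverse to the identity", {
  set.seed(13)
  for (i in 1:5) {
    rig <- rigid_transform(rotation = runif(3, -0.3, 0.3),
                           translation = runif(3, -20, 20),
                           center = runif(3, -50, 50))
    inv <- invert_rigid(rig)
    p <- matrix(runif(30, -100, 100), 10, 3)
    back <- transform_point(inv, transform_point(rig, p))
    expect_lt(max(abs(back - p)), 1e-9)
  }
})

test_that("transform_point handles identity, translation and composition", {
  expect_equal(transform_point(rigid_transform(), c(1, 2, 3)), c(1, 2, 3))
  tr <- rigid_transform(translation = c(3, 4, 0))
  expect_equal(transform_point(tr, c(0, 0, 0)), c(3, 4, 0))
  # composite with zero coefficients reduces to the rigid part
  img <- image_volume(array(0, c(20, 20, 12)), c(2, 2, 3))
  B <- init_bspline_grid(img, 15)
  Tc <- composite_transform(tr, B)
  expect_equal(transform_point(Tc, c(10, 10, 10)), c(13, 14, 10))
})

test_that("B-spline displacement satisfies partition of unity", {
  img <- image_volume(array(0, c(20, 20, 10)), c(2, 2, 4))
  B <- init_bspline_grid(img, 16)
  expect_equal(bspline_displacement(B, c(10, 10, 10)), matrix(0, 1, 3))
  B$coefficients[, , , 1] <- 2.5
  B$coefficients[, , , 2] <- -1
  B$coefficients[, , , 3] <- 0.25
  set.seed(17)
  pts <- cbind(runif(100, 0, 38), runif(100, 0, 38), runif(100, 0, 36))
  D <- bspline_displacement(B, pts)
  expect_lt(max(abs(sweep(D, 2, c(2.5, -1, 0.25)))), 1e-12)
})

test_that("B-spline displacement matches the dense basis-summation oracle", {
  img <- image_volume(array(0, c(20, 20, 10)), c(2, 2, 4))
  B <- init_bspline_grid(img, 16)
  set.seed(19)
  B$coefficients[] <- rnorm(length(B$coefficients), 0, 3)
  pts <- cbind(runif(100, 0, 38), runif(100, 0, 38), runif(100, 0, 36))
  D <- bspline_displacement(B, pts)
  for (i in seq(1, 100, by = 7))
    expect_lt(max(abs(D[i, ] - bspline_oracle(B, pts[i, ]))), 1e-10)
  # outside the support: domain error
  expect_error(bspline_displacement(B, c(-100, 0, 0)), "support")
})

test_that("grid initialisation honours the integer-interval rule", {
  # 300 mm extent, request 96 -> 4 intervals (spacing 75 <= 96), 8 points
  img <- image_volume(array(0, c(301, 301, 301)), c(1, 1, 1))
  B <- init_bspline_grid(img, 96)
  expect_equal(B$grid_size, rep(8L, 3))
  expect_equal(B$grid_spacing, rep(75, 3))
  expect_true(all(B$grid_spacing <= 96))
  # exact division: request 30 on 300 -> 10 intervals
  B2 <- init_bspline_grid(img, 30)
  expect_equal(B2$grid_size, rep(14L, 3))
  expect_equal(B2$grid_spacing, rep(30, 3))
  # degenerate extent
  flat <- image_volume(array(0, c(10, 10, 1)), c(1, 1, 1))
  expect_error(init_bspline_grid(flat, 5), "degenerate")
})

test_that("grid refinement reproduces the coarse field", {
  img <- image_volume(array(0, c(33, 33, 33)), c(3, 3, 3))
  B <- init_bspline_grid(img, 48)
  # zero field refines to a zero field
  Bz <- refine_bspline_grid(B, 24)
  expect_true(all(Bz$coefficients == 0))
  expect_gt(prod(Bz$grid_size), prod(B$grid_size))
  # dyadic halving is exact
  set.seed(23)
  B$coefficients[] <- rnorm(length(B$coefficients), 0, 5)
  Bh <- refine_bspline_grid(B, B$grid_spacing[1] / 2)
  pts <- cbind(runif(500, 0, 96), runif(500, 0, 96), runif(500, 0, 96))
  expect_lt(max(abs(bspline_displacement(B, pts) -
                      bspline_displacement(Bh, pts))), 1e-9)
  # non-dyadic refinement reproduces a smooth field within 0.05 mm
  Bq <- refine_bspline_grid(B, 30)
  pts2 <- cbind(runif(1000, 0, 96), runif(1000, 0, 96), runif(1000, 0, 96))
  expect_lt(max(abs(bspline_displacement(B, pts2) -
                      bspline_displacement(Bq, pts2))), 0.05)
  # refinement that cannot refine any axis errors
  expect_error(refine_bspline_grid(B, B$grid_spacing[1] * 2), "smaller")
  # memory guard
  expect_error(refine_bspline_grid(B, 1, max_points = 100), "budget")
})

test_that("dense displacement fields audit against transform_point", {
  img <- image_volume(array(0, c(12, 12, 8)), c(4, 4, 6))
  # identity -> zero field; pure translation -> constant field
  f0 <- dense_displacement_field(rigid_transform(), img)
  expect_true(all(f0 == 0))
  ft <- dense_displacement_field(rigid_transform(translation = c(1, -2, 3)), img)
  expect_equal(range(ft[, , , 1]), c(1, 1))
  expect_equal(range(ft[, , , 2]), c(-2, -2))
  expect_equal(range(ft[, , , 3]), c(3, 3))
  # random B-spline: field equals pointwise evaluation
  B <- init_bspline_grid(img, 20)
  set.seed(29)
  B$coefficients[] <- rnorm(length(B$coefficients))
  Tc <- composite_transform(rigid_transform(translation = c(2, 0, 0)), B)
  fb <- dense_displacement_field(Tc, img)
  p <- voxel_centers(img)
  sel <- sample(nrow(p), 100)
  q <- transform_point(Tc, p[sel, , drop = FALSE])
  flat <- matrix(fb, ncol = 3)
  expect_equal(flat[sel, ], q - p[sel, , drop = FALSE], tolerance = 1e-12)
})

test_that("transforms serialize to JSON and back", {
  img <- image_volume(array(0, c(16, 16, 10)), c(2, 2, 3))
  B <- init_bspline_grid(img, 12)
  set.seed(31)
  B$coefficients[] <- rnorm(length(B$coefficients))
  Tc <- composite_transform(
    rigid_transform(c(0.01, -0.02, 0.03), c(1, 2, 3), c(15, 15, 13)), B)
  f <- tempfile(fileext = ".json")
  write_transform(Tc, f)
  r <- read_transform(f)
  expect_equal(r$rigid$rotation, Tc$rigid$rotation)
  expect_equal(r$rigid$translation, Tc$rigid$translation)
  expect_equal(r$bspline$coefficients, B$coefficients)
  expect_equal(r$bspline$grid_spacing, B$grid_spacing)
  unlink(f)
})

test_that("rigid warp round-trips through the inverse transform", {
  ph <- preprocessed_test_phantom()
  sm <- gaussian_smooth(ph$image, c(5, 5, 3))  # interpolation bound needs a smooth image
  rig <- rigid_transform(c(0.02, 0, -0.03), c(4, -3, 2),
                         center = c(90, 90, 75))
  fwd <- warp_moving_image(sm, rig, sm)
  back <- warp_moving_image(fwd, invert_rigid(rig), sm)
  interior <- ph$body$voxels == 1
  # shrink the comparison region away from mask edges
  er <- gaussian_smooth(image_volume(array(as.double(interior),
                                           dim(interior)),
                                     sm$spacing), c(4, 4, 3))$voxels > 0.9999
  expect_lt(mean(abs(back$voxels[er] - sm$voxels[er])), 2)
})
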