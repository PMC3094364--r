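test_that("image_volume validates geometry and maps indices to mm", {
  v <- image_volume(array(-1000, c(10, 10, 5)), spacing = c(1, 1, 4),
                    origin = c(2, 3, 4))
  expect_equal(physical_extent(v, 3), c(4 - 2, 4 - 2 + 5 * 4))
  expect_equal(slice_centers(v, 3), 4 + (0:4) * 4)
  p <- voxel_centers(v)
  expect_equal(p[1, ], c(2, 3, 4))
  expect_equal(p[nrow(p), ], c(2 + 9, 3 + 9, 4 + 16))
  expect_error(image_volume(array(0, c(4, 4, 4)), c(1, 0, 1)), "positive")
  expect_error(image_volume(matrix(0, 3, 3), c(1, 1, 1)), "3D")
})

test_that("MetaImage and NIfTI files round-trip voxels and geometry", {
  set.seed(11)
  v <- image_volume(array(rnorm(10 * 10 * 5, -500, 300), c(10, 10, 5)),
                    spacing = c(1, 1, 4), origin = c(-5, 2, 10))
  for (ext in c(".mha", ".mhd", ".nii", ".nii.gz")) {
    f <- tempfile(fileext = ext)
    write_image(v, f)
    r <- read_image(f)
    expect_equal(r$voxels, v$voxels, info = ext)
    expect_equal(r$spacing, v$spacing, info = ext)
    expect_equal(r$origin, v$origin, info = ext)
    unlink(f)
  }
})

test_that("a 10x10x5 MetaImage with spacing (1,1,4) echoes its header", {
  v <- image_volume(array(0, c(10, 10, 5)), spacing = c(1, 1, 4))
  f <- tempfile(fileext = ".mha")
  write_image(v, f)
  expect_equal(read_image(f)$spacing, c(1, 1, 4))
  unlink(f)
})

test_that("NIfTI written here is read identically by the reference reader", {
  set.seed(3)
  v <- image_volume(array(rnorm(8 * 6 * 4), c(8, 6, 4)), c(2, 2, 3))
  f <- tempfile(fileext = ".nii.gz")
  write_image(v, f, "nifti")
  ref <- as.array(RNifti::readNifti(f))
  expect_equal(array(as.double(ref), dim(ref)), v$voxels)
  # and a file produced by the reference writer is read identically here
  g <- tempfile(fileext = ".nii")
  nii <- RNifti::asNifti(v$voxels)
  RNifti::pixdim(nii) <- v$spacing
  RNifti::writeNifti(nii, g, datatype = "double")
  expect_equal(read_image(g)$voxels, v$voxels)
  unlink(c(f, g))
})

test_that("compressed and uncompressed NIfTI encodings agree", {
  set.seed(5)
  v <- image_volume(array(rnorm(6 * 6 * 3), c(6, 6, 3)), c(1, 1, 1))
  f1 <- tempfile(fileext = ".nii")
  f2 <- tempfile(fileext = ".nii.gz")
  write_image(v, f1)
  write_image(v, f2)
  expect_equal(read_image(f1)$voxels, read_image(f2)$voxels)
  unlink(c(f1, f2))
})

test_that("unreadable files and unsupported formats raise clear errors", {
  expect_error(read_image("/nonexistent/file.mha"), "does not exist")
  v <- image_volume(array(0, c(4, 4, 4)), c(1, 1, 1))
  expect_error(write_image(v, tempfile(fileext = ".xyz")), "format")
})

test_that("landmark files round-trip and enforce unique labels", {
  m <- landmark_set(c("a", "b"), c(1, 2), c(3, 4), c(5, 6), frame = "kVCT")
  f <- tempfile(fileext = ".csv")
  write_landmarks(m, f)
  r <- read_landmarks(f, frame = "kVCT")
  expect_equal(landmark_matrix(r), landmark_matrix(m))
  expect_equal(r$label, m$label)
  expect_error(landmark_set(c("a", "a"), 1:2, 1:2, 1:2), "unique")
  unlink(f)
})

test_that("body masking recovers the analytic ellipsoid and drops the couch", {
  spec <- test_phantom_spec()
  ph <- generate_thorax_phantom(spec)
  body <- extract_body_mask(ph$image)
  p <- voxel_centers(ph$image)
  ctr <- (spec$dims - 1) * spec$spacing / 2
  rho <- sqrt(rowSums(sweep(p, 2, ctr, "-")^2 /
                        matrix(spec$body_semiaxes^2, nrow(p), 3, TRUE)))
  inside <- rho < 1
  # agreement up to a one-voxel boundary band
  band <- abs(rho - 1) < max(spec$spacing) / min(spec$body_semiaxes) * 2
  expect_true(all(body$voxels[inside & !band] == 1))
  expect_true(all(body$voxels[!inside & !band] == 0))
  # couch slab entirely excluded
  ext <- spec$dims * spec$spacing
  couch <- p[, 2] > 0.9 * ext[2] & p[, 2] < 0.95 * ext[2]
  expect_equal(sum(body$voxels[couch]), 0)
})

test_that("an all-air image is a degenerate input for body masking", {
  v <- image_volume(array(-1000, c(16, 16, 16)), c(1, 1, 1))
  expect_error(extract_body_mask(v), "degenerate")
})

test_that("mask_background is idempotent and fills outside the body", {
  ph <- preprocessed_test_phantom()
  once <- ph$image
  twice <- mask_background(once, ph$body)
  expect_identical(once$voxels, twice$voxels)
  expect_true(all(once$voxels[ph$body$voxels == 0] == -1000))
  # full mask leaves the image unchanged
  full <- new_mask(array(1L, img_dim(ph$raw)), ph$raw)
  expect_identical(mask_background(ph$raw, full)$voxels, ph$raw$voxels)
  # geometry mismatch is a contract error
  other <- image_volume(array(0, c(4, 4, 4)), c(1, 1, 1))
  expect_error(mask_background(other, ph$body), "geometry")
})

test_that("axial cropping follows the slice-center rule", {
  ref <- image_volume(array(0, c(4, 4, 90)), c(1, 1, 3.27))
  partner <- image_volume(array(0, c(4, 4, 20)), c(1, 1, 4), c(0, 0, 2))
  # partner extent: [0, 80) mm; reference centers 0, 3.27, ...
  cropped <- crop_axial_to_overlap(ref, partner)
  centers <- slice_centers(ref, 3)
  expect_equal(img_dim(cropped)[3], sum(centers >= 0 & centers < 80))
  expect_equal(cropped$spacing[1:2], ref$spacing[1:2])
  # covering partner: unchanged
  big <- image_volume(array(0, c(4, 4, 100)), c(1, 1, 4), c(0, 0, -10))
  expect_equal(img_dim(crop_axial_to_overlap(ref, big)), img_dim(ref))
  # disjoint: error
  far <- image_volume(array(0, c(4, 4, 5)), c(1, 1, 4), c(0, 0, 1e4))
  expect_error(crop_axial_to_overlap(ref, far), "overlap")
})

test_that("resampling matches integer-shift and analytic-ramp oracles", {
  set.seed(21)
  v <- image_volume(array(rnorm(12 * 12 * 8), c(12, 12, 8)), c(2, 2, 3))
  # identity on identical geometry
  id <- resample_to_reference(v, rigid_transform(), v)
  expect_equal(id$voxels, v$voxels)
  # pure translation by one voxel: shifted array with fill entering a face
  sh <- resample_to_reference(v, rigid_transform(translation = c(2, 0, 0)), v)
  expect_equal(sh$voxels[1:11, , ], v$voxels[2:12, , ])
  expect_true(all(sh$voxels[12, , ] == -1000))
  # half-voxel translation of a linear ramp equals the analytic ramp
  ramp <- image_volume(array(rep(2 * (0:11), times = 12 * 8), c(12, 12, 8)),
                       c(2, 2, 3))
  half <- resample_to_reference(ramp, rigid_transform(translation = c(1, 0, 0)),
                                ramp)
  expect_equal(half$voxels[1:11, , ],
               ramp$voxels[1:11, , ] + 1, tolerance = 1e-12)
})

test_that("gaussian smoothing matches a dense convolution oracle", {
  set.seed(31)
  d <- c(9, 9, 7)
  delta <- array(0, d)
  delta[5, 5, 4] <- 1
  img <- image_volume(delta, c(1, 1, 1))
  sm <- gaussian_smooth(img, c(2, 2, 2))
  expect_equal(sm$voxels, gaussian_oracle(delta, c(2, 2, 2)),
               tolerance = 1e-10)
  # zero kernel is the identity
  expect_identical(gaussian_smooth(img, c(0, 0, 0))$voxels, delta)
  # constants are preserved exactly (mean too)
  const <- image_volume(array(7.5, d), c(1, 1, 1))
  smc <- gaussian_smooth(const, c(3, 1, 2))
  expect_equal(smc$voxels, const$voxels, tolerance = 1e-12)
  expect_error(gaussian_smooth(img, c(-1, 0, 0)), "nonnegative")
})
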