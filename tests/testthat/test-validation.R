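make_img <- function(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  image_volume(array(arr, dim(arr)), spacing, origin)
}

test_that("correlation coefficient detects linear relations and trims borders", {
  set.seed(41)
  d <- c(70, 70, 10)
  a <- make_img(array(rnorm(prod(d), 0, 100), d))
  expect_equal(correlation_coefficient(a, a), 1)
  b <- make_img(2 * a$voxels + 100)
  expect_equal(correlation_coefficient(a, b), 1)
  # border voxels are excluded: corrupting them must not change CC
  corrupt <- a$voxels
  corrupt[1:30, , ] <- 1e6
  corrupt[, , 1:2] <- -1e6
  expect_equal(correlation_coefficient(a, make_img(corrupt)),
               correlation_coefficient(a, a))
  # affine intensity invariance in both arguments
  a2 <- make_img(0.5 * a$voxels - 250)
  set.seed(42)
  c2 <- make_img(a$voxels + rnorm(prod(d), 0, 50))
  expect_equal(correlation_coefficient(a2, c2),
               correlation_coefficient(a, c2), tolerance = 1e-12)
  expect_error(correlation_coefficient(a, make_img(array(0, d))), "constant")
})

test_that("correlation coefficient matches a direct formula evaluation", {
  # toy pair with a 4x4x1 interior (border 1 voxel in x/y, 1 slice in z)
  d <- c(6, 6, 3)
  set.seed(43)
  x <- array(rnorm(prod(d)), d)
  y <- array(rnorm(prod(d)), d)
  cc <- correlation_coefficient(make_img(x), make_img(y), border_xy = 1,
                                border_z = 1)
  xi <- as.numeric(x[2:5, 2:5, 2])
  yi <- as.numeric(y[2:5, 2:5, 2])
  direct <- sum((xi - mean(xi)) * (yi - mean(yi))) /
    sqrt(sum((xi - mean(xi))^2) * sum((yi - mean(yi))^2))
  expect_equal(cc, direct, tolerance = 1e-12)
})

test_that("landmark transformation preserves labels and reports exclusions", {
  m <- landmark_set(c("a", "b", "c"), c(10, 20, 30), c(10, 20, 30),
                    c(10, 20, 30), frame = "kVCT")
  t0 <- transform_landmarks(m, rigid_transform())
  expect_equal(landmark_matrix(t0), landmark_matrix(m))
  tt <- transform_landmarks(m, rigid_transform(translation = c(1, -2, 3)))
  expect_equal(landmark_matrix(tt),
               sweep(landmark_matrix(m), 2, c(1, -2, 3), "+"))
  # a landmark outside the B-spline support is excluded, not dropped silently
  img <- image_volume(array(0, c(20, 20, 20)), c(1, 1, 1))
  B <- init_bspline_grid(img, 10)
  far <- landmark_set(c("in", "out"), c(10, 500), c(10, 0), c(10, 0),
                      frame = "kVCT")
  tf <- transform_landmarks(far, composite_transform(rigid_transform(), B))
  expect_equal(tf$label, "in")
  expect_equal(attr(tf, "excluded"), "out")
})

test_that("target registration error summarises per-landmark distances", {
  ref <- landmark_set(c("a", "b"), c(0, 1), c(0, 1), c(0, 1), frame = "MVCT")
  expect_equal(target_registration_error(ref, ref)$mean, 0)
  off <- landmark_set("a", 3, 4, 0, frame = "MVCT")
  tgt <- landmark_set("a", 0, 0, 0, frame = "MVCT")
  expect_equal(target_registration_error(off, tgt)$per_landmark$tre_mm, 5)
  # three session means reported in a per-patient summary
  expect_equal(round(mean(c(2.42, 4.18, 4.11)), 2), 3.57)
  expect_error(target_registration_error(
    landmark_set("x", 1, 1, 1, frame = "MVCT"), tgt), "common")
})

test_that("region growing recovers phantom lungs and excludes exterior air", {
  ph <- preprocessed_test_phantom()
  seg <- segment_lungs_region_growing(ph$image, body = ph$body)
  truth <- ph$truth$lungs_fixed
  tr_all <- truth$left$voxels | truth$right$voxels
  # coverage: nearly all true lung voxels found
  expect_gt(sum(seg$voxels & tr_all) / sum(tr_all), 0.97)
  # nothing outside the body (exterior air is border-connected)
  expect_equal(sum(seg$voxels[ph$body$voxels == 0]), 0)
  # body-only image: empty-segmentation error
  solid <- image_volume(array(c(-1000, 0)[1 +
    (ell_test_ball(c(24, 24, 12), c(1, 1, 1)) < 1)], c(24, 24, 12)),
    c(1, 1, 1))
  expect_error(segment_lungs_region_growing(solid), "empty")
})

test_that("left/right splitting follows centroid x and handles fusion", {
  d <- c(40, 40, 20)
  img <- image_volume(array(0, d), c(2, 2, 2))
  p <- voxel_centers(img)
  two <- (sqrt(rowSums(sweep(p, 2, c(55, 40, 20), "-")^2)) < 12) |
    (sqrt(rowSums(sweep(p, 2, c(25, 40, 20), "-")^2)) < 12)
  m <- new_mask(array(two, d), img)
  lr <- split_left_right(m)
  expect_equal(attr(lr$left, "side"), "left")
  expect_gt(mask_centroid_x(lr$left), mask_centroid_x(lr$right))
  # fused blob: mid-sagittal plane split gives ~equal halves
  fused <- new_mask(array(sqrt(rowSums(sweep(p, 2, c(39, 40, 20), "-")^2)) < 20,
                          d), img)
  lrf <- split_left_right(fused)
  v1 <- sum(lrf$left$voxels)
  v2 <- sum(lrf$right$voxels)
  expect_lt(abs(v1 - v2) / max(v1, v2), 0.05)
})

test_that("common-extent restriction halves a uniform slab's volume", {
  d <- c(10, 10, 20)
  img <- image_volume(array(0, d), c(1, 1, 2))
  m <- new_mask(array(1L, d), img)
  r <- restrict_to_common_extent(m, m, fov_z = c(-1, 19))
  # identical FOVs covering everything: unchanged
  full <- restrict_to_common_extent(m, m)
  expect_equal(sum(full$a$voxels), sum(m$voxels))
  # half the z extent retains half the slices (within one slice)
  expect_lt(abs(sum(r$a$voxels) / sum(m$voxels) - 0.5), 1 / d[3] + 1e-9)
  expect_error(restrict_to_common_extent(m, m, fov_z = c(100, 50)), "empty")
})

test_that("lung volume is count times voxel volume", {
  d <- c(20, 20, 10)
  img <- image_volume(array(0, d), c(1, 1, 4))
  v <- array(0L, d)
  v[seq_len(1000)] <- 1L
  expect_equal(lung_volume(new_mask(v, img)), 4000)
  expect_equal(lung_volume(new_mask(array(0L, d), img)), 0)
  # phantom ellipsoid volume is close to (4/3) pi a b c
  ph <- preprocessed_test_phantom()
  vol <- lung_volume(ph$truth$lungs_fixed$right)
  sp <- ph$truth$spec
  expect_lt(abs(vol - 4 / 3 * pi * prod(sp$lung_semiaxes)) /
              (4 / 3 * pi * prod(sp$lung_semiaxes)), 0.02)
})

test_that("volume error follows the published worked example", {
  expect_equal(volume_error(100, 100), 0)
  expect_equal(round(volume_error(632.39, 475.22), 2), 24.85)
  expect_equal(round(volume_error(632.39, 619.95), 2), 1.97)
  expect_error(volume_error(0, 10), "positive")
})

test_that("centroid error equals known shifts and behaves as a metric", {
  d <- c(30, 30, 10)
  img <- image_volume(array(0, d), c(0.2, 0.2, 1))
  blob <- array(0L, d)
  blob[10:15, 10:15, 4:6] <- 1L
  a <- new_mask(blob, img)
  expect_equal(centroid_error(a, a), 0)
  # on-grid translation by (0.6, 0.8, 0) mm = (3, 4) voxels
  shifted <- array(0L, d)
  shifted[13:18, 14:19, 4:6] <- 1L
  b <- new_mask(shifted, img)
  expect_equal(centroid_error(a, b), 1.0, tolerance = 1e-9)
  # symmetry and triangle inequality
  set.seed(47)
  blobs <- lapply(1:3, function(i) {
    v <- array(0L, d)
    v[sample(prod(d), 200)] <- 1L
    new_mask(v, img)
  })
  expect_equal(centroid_error(blobs[[1]], blobs[[2]]),
               centroid_error(blobs[[2]], blobs[[1]]))
  expect_lte(centroid_error(blobs[[1]], blobs[[3]]),
             centroid_error(blobs[[1]], blobs[[2]]) +
               centroid_error(blobs[[2]], blobs[[3]]) + 1e-12)
})

test_that("Jaccard index implements set overlap", {
  d <- c(20, 20, 5)
  img <- image_volume(array(0, d), c(1, 1, 1))
  a <- array(0L, d); a[1:100] <- 1L
  b <- array(0L, d); b[51:150] <- 1L
  ma <- new_mask(a, img); mb <- new_mask(b, img)
  expect_equal(jaccard_index(ma, ma), 1)
  expect_equal(jaccard_index(ma, mb), 50 / 150)
  expect_equal(jaccard_index(ma, mb), jaccard_index(mb, ma))
  disj <- array(0L, d); disj[201:300] <- 1L
  expect_equal(jaccard_index(ma, new_mask(disj, img)), 0)
  empty <- new_mask(array(0L, d), img)
  expect_error(jaccard_index(empty, empty), "empty")
})

test_that("exact Wilcoxon p-values match full 2^n enumeration", {
  # constant positive shift, n = 15: the extreme two-sided case
  rigid <- c(5.16, 9.17, 6.43, 3.2, 4.2, 4.4, 6.41, 2.93, 4.44, 5.39, 7.95,
             9.86, 3.08, 2.87, 2.99)
  elastic <- rigid + 1
  w <- wilcoxon_signed_rank(rigid, elastic)
  expect_match(w$method, "exact")
  expect_equal(w$p_value, 2 / 2^15)
  expect_equal(w$p_value, 6.1e-5, tolerance = 0.01)
  # hand-made n = 6 tables against the enumeration oracle
  set.seed(53)
  for (i in 1:5) {
    a <- round(runif(6, 0, 10), 2)
    b <- round(a + rnorm(6, 0.5, 1.5), 2)
    if (any(b == a)) next
    w <- wilcoxon_signed_rank(a, b)
    expect_equal(w$p_value, wilcoxon_enumeration_oracle(b - a),
                 tolerance = 1e-12, info = paste("case", i))
  }
  # antisymmetric differences sit at the null center
  a <- c(1, 2, 3, 4, 5, 6)
  b <- a + c(1, -1, 2, -2, 3, -3)
  w <- wilcoxon_signed_rank(a, b)
  expect_equal(w$p_value, 1)
  expect_error(wilcoxon_signed_rank(a, a), "degenerate")
  expect_error(wilcoxon_signed_rank(1:4, 2:5), "5 pairs")
})

test_that("ties and large n fall back to the corrected normal approximation", {
  a <- rep(c(1, 2, 3), 10)
  b <- a + rep(c(0.5, -0.5, 1), 10)
  w <- wilcoxon_signed_rank(a, b)
  expect_equal(w$method, "normal approximation")
  ref <- suppressWarnings(stats::wilcox.test(b, a, paired = TRUE))
  expect_equal(w$p_value, unname(ref$p.value), tolerance = 1e-10)
})

test_that("cohort aggregation reproduces its rows arithmetically", {
  ref <- reference_cohort()
  agg <- aggregate_cohort(ref)
  # per-patient TRE: mean/SD of session means, max of maxima
  p1 <- dplyr::filter(agg$tre_by_patient, patient == 1, stage == "elastic")
  expect_equal(p1$tre_mean, mean(c(2.42, 4.18, 4.11)))
  expect_equal(p1$tre_sd, sd(c(2.42, 4.18, 4.11)))
  expect_equal(p1$tre_max, 7.28)
  # pooled lung means recompute from the 30 cells
  lr <- dplyr::filter(ref$lung, stage == "rigid")
  expect_equal(dplyr::filter(agg$lung_summary, stage == "rigid")$mean_abs_ve,
               mean(abs(lr$ve_percent)))
  # Wilcoxon table present for all metrics
  expect_true(all(c("cc", "tre_mean", "abs_ve", "ce", "jac") %in%
                    agg$wilcoxon$metric))
  expect_true(all(agg$wilcoxon$p_value < 0.05))
})
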