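# Shared fixtures and independent oracles, all generated in code.

# small thorax phantom sized for test runtimes; anatomy scaled to the grid
test_phantom_spec <- function(dims = c(64, 64, 32), spacing = c(3, 3, 5),
                              seed = 4L, ...) {
  phantom_spec(dims = dims, spacing = spacing,
               body_semiaxes = c(70, 55, 110),
               lung_semiaxes = c(22, 34, 58),
               lung_offset = c(30, -4, 0),
               bone_radius = 10, seed = seed, ...)
}

# cubic B-spline kernel, independent implementation
b3_oracle <- function(t) {
  a <- abs(t)
  ifelse(a >= 2, 0, ifelse(a < 1, (4 - 6 * a^2 + 3 * a^3) / 6, (2 - a)^3 / 6))
}

# dense tensor-product B-spline displacement: triple loop over all control
# points (no neighbourhood shortcuts)
bspline_oracle <- function(B, p) {
  out <- c(0, 0, 0)
  u <- (p - B$grid_origin) / B$grid_spacing
  for (i in seq_len(B$grid_size[1]))
    for (j in seq_len(B$grid_size[2]))
      for (k in seq_len(B$grid_size[3])) {
        w <- b3_oracle(u[1] - (i - 1)) * b3_oracle(u[2] - (j - 1)) *
          b3_oracle(u[3] - (k - 1))
        if (w > 0) out <- out + w * B$coefficients[i, j, k, ]
      }
  out
}

# dense Parzen joint-histogram mutual information, mirroring the metric's
# definition with plain R loops (zero-order fixed window, cubic moving window)
mattes_mi_oracle <- function(fvals, mvals, n_bins, frange, mrange) {
  nb <- n_bins
  if (diff(frange) == 0 || diff(mrange) == 0) return(0)
  bwf <- diff(frange) / nb
  bwm <- diff(mrange) / (nb - 5)
  W <- matrix(0, nb, nb)
  for (k in seq_along(fvals)) {
    fb <- min(nb - 1, max(0, floor((fvals[k] - frange[1]) / bwf)))
    m <- min(nb - 3, max(2, (mvals[k] - mrange[1]) / bwm + 2))
    j0 <- floor(m) - 1
    for (j in j0:(j0 + 3))
      W[fb + 1, j + 1] <- W[fb + 1, j + 1] + b3_oracle(j - m) / length(fvals)
  }
  pf <- rowSums(W)
  pm <- colSums(W)
  mi <- 0
  for (a in seq_len(nb))
    for (b in seq_len(nb))
      if (W[a, b] > 0) mi <- mi + W[a, b] * log(W[a, b] / (pf[a] * pm[b]))
  -mi
}

# exhaustive two-sided signed-rank p-value over all 2^n sign assignments
wilcoxon_enumeration_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  V_all <- as.numeric(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- mean(abs(V_all - mu) >= abs(V_obs - mu) - 1e-12)
  p
}

# dense separable-Gaussian convolution oracle (direct triple sum with edge
# replication), independent of the compiled path
gaussian_oracle <- function(arr, sigma) {
  d <- dim(arr)
  out <- arr
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- ceiling(3 * s)
    k <- exp(-0.5 * ((-r):r)^2 / s^2)
    k <- k / sum(k)
    res <- array(0, d)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
      acc <- 0
      for (o in (-r):r) {
        idx <- c(i, j, l)
        idx[ax] <- min(max(idx[ax] + o, 1), d[ax])
        acc <- acc + k[o + r + 1] * out[idx[1], idx[2], idx[3]]
      }
      res[i, j, l] <- acc
    }
    out <- res
  }
  out
}

# phantom pair with a known rigid offset (moving = fixed moved by `rig`)
shifted_pair <- function(fx, rig) {
  mv <- resample_to_reference(fx, invert_rigid(rig), fx)
  mv$modality <- "MVCT"
  mv
}

preprocessed_test_phantom <- function(...) {
  ph <- generate_thorax_phantom(test_phantom_spec(...))
  body <- extract_body_mask(ph$image)
  list(image = mask_background(ph$image, body), body = body,
       truth = ph$truth, raw = ph$image)
}

# normalised radius field of a centered ball (for body-only segmentation case)
ell_test_ball <- function(d, spacing) {
  img <- image_volume(array(0, d), spacing)
  p <- voxel_centers(img)
  ctr <- (d - 1) * spacing / 2
  array(sqrt(rowSums(sweep(p, 2, ctr, "-")^2)) / (min(d * spacing) * 0.4), d)
}

mask_centroid_x <- function(m) {
  idx <- which(m$voxels > 0)
  d <- dim(m$voxels)
  i <- (idx - 1) %% d[1]
  m$origin[1] + mean(i) * m$spacing[1]
}

# trilinear probe of a scalar field at physical points
cpp_field_probe <- function(field, geom, pts) {
  r <- mvctreg:::cpp_trilinear(array(field, dim(field)), dim(field),
                               geom$spacing, geom$origin, pts, 0, FALSE)
  r$values
}

field_min_jacobian_helper <- function(field, spacing) {
  mvctreg:::field_min_jacobian(field, spacing)
}
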