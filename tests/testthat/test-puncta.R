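test_that("detect_objects recovers well-separated synthetic spots exactly", {
  g <- gen_cell_mask("circle", radius = 80, image_size = c(200, 200))
  p <- gen_puncta_stack(g, n = 10, sigma = 2, min_separation = 20,
                        noise_sd = 0, seed = 21)
  det <- detect_objects(p$stack)
  expect_equal(nrow(det$objects), 10)
  # centroids land near the true centers (um)
  d <- as.matrix(dist(rbind(p$truth$centers[, 1:2],
                            cbind(det$objects$x_um, det$objects$y_um))))
  cross <- d[1:10, 11:20]
  expect_lt(max(apply(cross, 1, min)), 0.05)  # within half a pixel

  empty <- image_stack(array(0, c(32, 32, 3)))
  expect_equal(nrow(detect_objects(empty)$objects), 0)
})

test_that("two nearby spots merge into one object", {
  g <- gen_cell_mask("circle", radius = 40, image_size = c(96, 96))
  vox <- array(0, c(96, 96, 3))
  for (off in c(0, 1.5)) {  # separation < 1 sigma (sigma = 2)
    cx <- 47 + off
    for (r in 1:96) for (cc in 1:96)
      vox[r, cc, 2] <- vox[r, cc, 2] +
        1000 * exp(-(((cc - 1) - cx)^2 + ((r - 1) - 47)^2) / (2 * 2^2))
  }
  det <- detect_objects(image_stack(vox), threshold = 100)
  expect_equal(nrow(det$objects), 1)
})

test_that("graph labeling matches the flood-fill oracle on random stacks", {
  set.seed(42)
  for (i in 1:12) {
    dims <- sample(8:32, 3, replace = TRUE)
    fg <- array(runif(prod(dims)) < runif(1, 0.05, 0.4), dims)
    conn <- sample(c(6, 18, 26), 1)
    ours <- astroquant:::label_components_3d(fg, conn)
    oracle <- flood_fill_label_3d(fg, conn)
    expect_true(same_partition(ours, oracle))
  }
})

test_that("density normalization is exact and linear", {
  expect_equal(density_per_100um2(50, 1000), 5)
  expect_equal(density_per_100um2(0, 1000), 0)
  expect_equal(density_per_100um2(50, 2000), density_per_100um2(50, 1000) / 2)
  expect_error(density_per_100um2(5, 0), "positive")
})

test_that("FWHM sizing matches closed forms", {
  # isotropic Gaussian sigma = 2 px at 0.1 um/px
  g <- gen_cell_mask("circle", radius = 60, image_size = c(160, 160),
                     pixel_size = 0.1)
  p <- gen_puncta_stack(g, n = 1, sigma = 2, noise_sd = 0, seed = 3)
  det <- detect_objects(p$stack)
  f <- fwhm_diameter(p$stack, det, det$objects$id[1])
  expect_lt(abs(f$diameter / 0.47096 - 1), 0.02)

  # anisotropic Gaussian: diameter is the mean of the axis FWHMs
  vox <- array(0, c(64, 64, 3))
  for (r in 1:64) for (cc in 1:64)
    vox[r, cc, 2] <- 1000 * exp(-(((cc - 1) - 31)^2 / (2 * 2^2) +
                                  ((r - 1) - 31)^2 / (2 * 4^2)))
  st <- image_stack(vox, pixel_size = 1)
  det2 <- detect_objects(st, threshold = 50)
  f2 <- fwhm_diameter(st, det2, 1, window_px = 20)
  expect_lt(abs(f2$diameter / (2.3548 * 3) - 1), 0.02)

  # top-hat disk radius 5 px: fwhm = 2R within a pixel
  vox3 <- array(0, c(64, 64, 3))
  for (r in 1:64) for (cc in 1:64)
    if (((cc - 1) - 31)^2 + ((r - 1) - 31)^2 <= 25) vox3[r, cc, 2] <- 500
  det3 <- detect_objects(image_stack(vox3, pixel_size = 1), threshold = 10)
  f3 <- fwhm_diameter(image_stack(vox3, pixel_size = 1), det3, 1)
  expect_lte(abs(f3$diameter - 10), 1)

  # a plateau never crossing half max inside the window is unmeasurable
  flat <- array(0, c(64, 64, 1)); flat[10:60, 10:60, 1] <- 100
  detf <- detect_objects(image_stack(flat, pixel_size = 1), threshold = 10)
  ff <- fwhm_diameter(image_stack(flat, pixel_size = 1), detf, 1, window_px = 10)
  expect_false(ff$measurable)
})
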