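test_that("skeleton segment decomposition recovers simple figures", {
  # single bar at 30 degrees
  g <- gen_cell_mask("circle", radius = 60, image_size = c(160, 160))
  img <- gen_filament_image(g, n_filaments = 1, mean_angle = 30,
                            concentration = 1e8, width = 3,
                            length_range = c(60, 60), seed = 2)
  segs <- skeletonize_segments((z_project(img$stack) > 0) + 0L)
  expect_equal(nrow(segs), 1)
  expect_lt(acute_diff <- min(abs(segs$orientation - 30),
                              180 - abs(segs$orientation - 30)), 2)

  # plus-sign cross decomposes into arms at 0 and 90
  cross <- matrix(0L, 80, 80)
  cross[39:41, 10:70] <- 1L
  cross[10:70, 39:41] <- 1L
  cs <- skeletonize_segments(cross)
  expect_gte(nrow(cs), 2)
  ang <- pmin(cs$orientation %% 90, 90 - cs$orientation %% 90)
  expect_true(all(ang < 3))

  expect_equal(nrow(skeletonize_segments(matrix(0L, 10, 10))), 0)
})

test_that("avg_theta matches analytic values", {
  par_segs <- data.frame(length_px = c(10, 20), orientation = c(25, 25))
  expect_equal(avg_theta(par_segs, 25), 0)
  perp <- data.frame(length_px = 5, orientation = 115)
  expect_equal(avg_theta(perp, 25), 90)
  set.seed(31)
  unif <- data.frame(length_px = 1, orientation = runif(1e4, 0, 180))
  expect_lt(abs(avg_theta(unif, 0) - 45), 1)
  expect_warning(res <- avg_theta(unif[0, ], 0), "no segments")
  expect_true(is.na(res))
})

test_that("parallelness spans its limits", {
  same <- data.frame(length_px = c(3, 9), orientation = c(70, 70))
  expect_equal(parallelness(same), 1)
  ortho <- data.frame(length_px = c(1, 1), orientation = c(0, 90))
  expect_equal(parallelness(ortho), 0, tolerance = 1e-12)
  set.seed(5)
  unif <- data.frame(length_px = 1, orientation = runif(1e4, 0, 180))
  expect_lt(parallelness(unif), 0.05)
})

test_that("bundling skewness matches the two-pass oracle and closed forms", {
  set.seed(12)
  img <- matrix(rexp(1e5), 250, 400)
  region <- matrix(1L, 250, 400)
  g1 <- bundling_skewness(img, region)
  expect_equal(g1, skewness_two_pass(as.numeric(img)), tolerance = 1e-9)
  expect_lt(abs(g1 - 2), 0.05)  # exponential population skewness = 2

  sym <- matrix(rep(c(0, 10), 5000), 100, 100)
  expect_lt(abs(bundling_skewness(sym, matrix(1L, 100, 100))), 0.05)
  expect_warning(res <- bundling_skewness(matrix(5, 10, 10), matrix(1L, 10, 10)),
                 "zero")
  expect_true(is.na(res))
})

test_that("higher orientation concentration raises parallelness monotonically", {
  g <- gen_cell_mask("circle", radius = 70, image_size = c(180, 180))
  med_par <- sapply(c(0, 2, 8, 32), function(conc) {
    median(sapply(1:8, function(s) {
      fil <- gen_filament_image(g, n_filaments = 60, mean_angle = 30,
                                concentration = conc, seed = s)
      segs <- data.frame(length_px = fil$truth$lengths,
                         orientation = fil$truth$orientations)
      parallelness(segs)
    }))
  })
  expect_true(all(diff(med_par) > 0))
})

test_that("avg_theta and parallelness survive an exact 90-degree rotation", {
  g <- gen_cell_mask("circle", radius = 60, image_size = c(160, 160))
  fil <- gen_filament_image(g, n_filaments = 40, mean_angle = 25,
                            concentration = 5, width = 2, seed = 17)
  img <- z_project(fil$stack)
  rot <- t(img)[, nrow(img):1]  # exact 90-degree rotation
  thr <- median(img[img > 0])
  s1 <- skeletonize_segments((img > thr) + 0L)
  s2 <- skeletonize_segments((rot > thr) + 0L)
  a1 <- avg_theta(s1, 25)
  a2 <- avg_theta(s2, 25 + 90)
  expect_lt(abs(a1 - a2) / max(a1, 1), 0.02)
  expect_lt(abs(parallelness(s1) - parallelness(s2)), 0.02)
})

test_that("filament_metrics composes per-cell outputs", {
  g <- gen_cell_mask("ellipse", semi_axes = c(70, 40), angle = 20,
                     image_size = c(192, 192))
  fil <- gen_filament_image(g, n_filaments = 80, mean_angle = 20,
                            concentration = 10, seed = 4)
  fm <- filament_metrics(fil$stack, g)
  expect_true(fm$avg_theta >= 0 && fm$avg_theta <= 90)
  expect_lt(fm$avg_theta, 30)           # filaments roughly along the axis
  expect_gt(fm$parallelness, 0.5)
  expect_true(is.finite(fm$bundling_skewness))
  expect_true(fm$occupancy_spl >= 0 && fm$occupancy_spl <= 100)
  expect_true(fm$occupancy_pn >= 0 && fm$occupancy_pn <= 100)
})
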