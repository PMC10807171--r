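test_that("generators are deterministic under a fixed seed", {
  g1 <- gen_cell_mask("blob", radius = 60, image_size = c(192, 192), seed = 11)
  g2 <- gen_cell_mask("blob", radius = 60, image_size = c(192, 192), seed = 11)
  expect_identical(g1$cell_mask, g2$cell_mask)

  p1 <- gen_puncta_stack(g1, n = 5, seed = 4)
  p2 <- gen_puncta_stack(g1, n = 5, seed = 4)
  expect_identical(p1$stack$voxels, p2$stack$voxels)
  expect_identical(p1$truth$centers, p2$truth$centers)

  f1 <- gen_filament_image(g1, n_filaments = 30, seed = 9)
  f2 <- gen_filament_image(g1, n_filaments = 30, seed = 9)
  expect_identical(f1$stack$voxels, f2$stack$voxels)

  e1 <- gen_expression(n_genes = 10, n_samples = 20, seed = 2)
  e2 <- gen_expression(n_genes = 10, n_samples = 20, seed = 2)
  expect_identical(e1$matrix, e2$matrix)
})

test_that("cell mask generator honours analytic areas and construction", {
  g <- gen_cell_mask("circle", radius = 100, image_size = c(256, 256),
                     pixel_size = 0.1)
  expect_lt(abs(sum(g$cell_mask) / (pi * 100^2) - 1), 0.005)

  ge <- gen_cell_mask("ellipse", semi_axes = c(100, 50), angle = 30,
                      image_size = c(256, 256))
  expect_equal(ge$long_axis_angle, 30)
  expect_lt(abs(long_axis(ge$cell_mask)$angle - 30), 1)

  expect_error(gen_cell_mask("circle", radius = 200, image_size = c(256, 256)),
               "bounds")
  # nucleus strictly inside cell
  expect_true(all(g$nucleus_mask <= g$cell_mask))
  expect_gt(sum(g$nucleus_mask), 0)
})

test_that("puncta generator respects count, separation and placement limits", {
  g <- gen_cell_mask("circle", radius = 80, image_size = c(200, 200))
  p <- gen_puncta_stack(g, n = 10, sigma = 2, min_separation = 20,
                        noise_sd = 0, seed = 5)
  expect_equal(nrow(p$truth$centers), 10)
  d <- as.matrix(dist(p$truth$centers_px))
  expect_true(all(d[upper.tri(d)] >= 20))
  # all centers inside the mask
  rc <- cbind(round(p$truth$centers_px[, 2]) + 1, round(p$truth$centers_px[, 1]) + 1)
  expect_true(all(g$cell_mask[rc] == 1))
  # empty, noiseless stack is uniform background
  p0 <- gen_puncta_stack(g, n = 0, noise_sd = 0, seed = 1)
  expect_true(all(p0$stack$voxels == 0))
  # impossible packing fails loudly
  expect_error(gen_puncta_stack(g, n = 50, min_separation = 60,
                                max_tries = 20, seed = 1),
               "could not place")
})

test_that("rendered spots have the Gaussian FWHM 2.3548 sigma", {
  g <- gen_cell_mask("circle", radius = 80, image_size = c(200, 200),
                     pixel_size = 0.1)
  p <- gen_puncta_stack(g, n = 6, sigma = 2, min_separation = 30,
                        noise_sd = 0, seed = 8)
  det <- detect_objects(p$stack)
  di <- measure_diameters(p$stack, det)
  expect_equal(nrow(di), 6)
  # FWHM = 2 sqrt(2 ln 2) sigma = 4.7096 px = 0.47096 um at 0.1 um/px;
  # sub-pixel spot centres leave a small per-spot discretization scatter,
  # so the bias is assessed on the mean over spots
  expect_lt(abs(mean(di$diameter) / 0.47096 - 1), 0.02)
  expect_lt(max(abs(di$diameter / 0.47096 - 1)), 0.05)
})

test_that("filament orientations follow the requested concentration", {
  g <- gen_cell_mask("circle", radius = 80, image_size = c(200, 200))
  tight <- gen_filament_image(g, n_filaments = 50, mean_angle = 40,
                              concentration = 1e6, seed = 3)
  expect_lt(max(abs(tight$truth$orientations - 40)), 1)
  unif <- gen_filament_image(g, n_filaments = 3000, concentration = 0, seed = 3)
  segs <- data.frame(length_px = 1, orientation = unif$truth$orientations)
  expect_lt(abs(avg_theta(segs, 0) - 45), 3)
})

test_that("gap series closes at width/(2v) with the analytic early slope", {
  gs <- gen_gap_series(gap_width = 500, gap_length = 1000, v_true = 10,
                       dt = 1, duration = 28, noise_sd = 0)
  closed <- gs$times[gs$areas == 0]
  expect_equal(min(closed), 25)  # width/(2v)
  early <- lm(gs$areas[1:4] ~ gs$times[1:4])
  expect_equal(unname(coef(early)[2]), -20000)
  flat <- gen_gap_series(v_true = 0, noise_sd = 0)
  expect_true(all(flat$areas == flat$areas[1]))
})

test_that("calcein trace generator produces the documented pieces", {
  # no swelling + bleach: strictly linear decline
  tr <- gen_calcein_trace(Fmax_pct = 100, bleach_slope = -0.5, noise_sd = 0)
  expect_equal(diff(tr$trace$F), rep(-0.5, length(tr$trace$F) - 1))
  # noiseless swelling phase equals the logistic exactly
  tr2 <- gen_calcein_trace(F0_level = 500, Fmax_pct = 140, k_true = 0.5,
                           t0_true = 40, rvd_rate = 0, noise_sd = 0)
  tt <- tr2$trace$times
  sw <- tt >= 30 & tt <= tr2$truth$t_peak
  expect_equal(tr2$trace$F[sw],
               500 * (140 / (1 + exp(-0.5 * (tt[sw] - 40)))) / 100)
  # baseline sits at F0
  expect_true(all(tr2$trace$F[tt < 30] == 500))
})

test_that("track generator records the true path length", {
  tk <- gen_tracks(n_steps = 10, step_length = 5, dt = 4, seed = 2)
  expect_equal(tk$truth$total_distance, 50)
  expect_equal(tk$truth$avg_speed, 1.25)
  m <- track_mobility(tk$track)
  expect_equal(m$total_distance, 50)
  expect_equal(m$avg_speed, 1.25)
  z <- gen_tracks(n_steps = 5, step_length = 0, dt = 1, seed = 1)
  expect_equal(track_mobility(z$track)$total_distance, 0)
})

test_that("expression generator yields the designated correlated pair", {
  e <- gen_expression(n_genes = 20, n_samples = 200, slope_true = 0.5,
                      noise_sd = 0, seed = 6)
  fit <- suppressWarnings(regress_pair(e$matrix["GX", ], e$matrix["GY", ]))
  expect_equal(fit$slope, 0.5, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("estimator error grows monotonically with generator noise", {
  noise_levels <- c(0, 1000, 5000, 20000, 60000)
  mean_err <- sapply(noise_levels, function(ns) {
    errs <- sapply(1:20, function(s) {
      gs <- gen_gap_series(v_true = 10, noise_sd = ns, seed = s)
      abs(analyze_gap_closure(gs)$v_migration - 10)
    })
    mean(errs)
  })
  expect_gt(cor(seq_along(noise_levels), mean_err, method = "spearman"), 0)
})
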