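test_that("shrink_outline reaches analytic targets on simple shapes", {
  disk <- gen_cell_mask("circle", radius = 100, image_size = c(256, 256))$cell_mask
  inner <- shrink_outline(disk, 0.8)
  expect_lt(abs(attr(inner, "achieved_fraction") - 0.8), 0.005)
  # inner radius should be ~ 100 sqrt(0.8)
  expect_lt(abs(sqrt(sum(inner) / pi) - 100 * sqrt(0.8)), 1)

  sq <- matrix(0L, 256, 256); sq[29:228, 29:228] <- 1L
  in_sq <- shrink_outline(sq, 0.9)
  expect_lt(abs(sqrt(sum(in_sq)) - 200 * sqrt(0.9)), 1)

  expect_identical(shrink_outline(disk, 1)[, ], disk)
  # a 1-px-thin line cannot be shrunk to 50% by erosion
  thin <- matrix(0L, 64, 64); thin[32, 5:60] <- 1L
  expect_error(shrink_outline(thin, 0.5), "achievable")
})

test_that("subplasmalemmal band partitions the cell at the target ratio", {
  geom <- gen_cell_mask("circle", radius = 100, image_size = c(256, 256))
  for (fr in c(0.8, 0.9)) {
    rs <- subplasmalemmal_band(geom, fr)
    expect_lt(abs(sum(rs$band) / sum(geom$cell_mask) - (1 - fr)), 0.005)
    expect_equal(rs$band + rs$inner, geom$cell_mask,
                 ignore_attr = TRUE)                    # exact partition
    expect_true(all(rs$band * rs$inner == 0))
  }
})

test_that("band/inner partition holds over random irregular shapes", {
  for (s in 1:50) {
    geom <- gen_cell_mask("blob", radius = 60, image_size = c(192, 192),
                          irregularity = 0.25, seed = s)
    rs <- subplasmalemmal_band(geom, 0.8)
    expect_equal(rs$band + rs$inner, geom$cell_mask, ignore_attr = TRUE)
    expect_lt(abs(attr(rs$inner, "achieved_fraction") - 0.8), 0.005)
  }
})

test_that("perinuclear region doubles the nuclear area and clips gracefully", {
  geom <- gen_cell_mask("circle", radius = 100, nucleus_fraction = 0.3,
                        image_size = c(256, 256))
  pn <- perinuclear_region(geom)
  expect_lt(abs(attr(pn, "area_ratio") - 2), 0.04)
  expect_false(attr(pn, "clipped"))
  expect_true(all(pn >= geom$nucleus_mask))      # nucleus included
  expect_true(all(pn <= geom$cell_mask))         # clipped to the cell
  # unclipped region ~ disk of radius r sqrt(2)
  expect_lt(abs(sqrt(sum(pn) / pi) - 30 * sqrt(2)), 1)

  # nucleus nearly filling the cell: region = cell, flagged
  big <- gen_cell_mask("circle", radius = 60, nucleus_fraction = 0.9,
                       image_size = c(160, 160))
  pn2 <- perinuclear_region(big)
  expect_true(attr(pn2, "clipped"))
  expect_identical(pn2[, ], big$cell_mask)

  nuc_free <- cell_geometry(geom$cell_mask, NULL)
  expect_error(perinuclear_region(nuc_free), "nucleus")
})

test_that("occupancy counts supra-threshold pixels in the region", {
  region <- matrix(1L, 10, 10)
  img <- matrix(0, 10, 10); img[, 1:5] <- 10
  expect_equal(as.numeric(occupancy(img, region, threshold = 5)), 50)
  expect_equal(as.numeric(occupancy(img + 100, region, threshold = 5)), 100)
  expect_equal(as.numeric(occupancy(img * 0, region, threshold = 5)), 0)
  # pixels outside the region are irrelevant
  img2 <- img; img2[region == 0] <- 1e6
  expect_equal(as.numeric(occupancy(img2, region, threshold = 5)),
               as.numeric(occupancy(img, region, threshold = 5)))
  expect_error(occupancy(img, matrix(0L, 10, 10), threshold = 5), "empty")
})

test_that("long axis identifies orientation and degeneracy", {
  bar <- matrix(0L, 64, 64); bar[30:34, 5:60] <- 1L
  la <- long_axis(bar)
  expect_lt(min(la$angle, 180 - la$angle), 1)
  disk <- gen_cell_mask("circle", radius = 25, image_size = c(64, 64))$cell_mask
  expect_true(long_axis(disk)$degenerate)
})
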