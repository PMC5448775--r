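test_that("planimetry reproduces hand-computable stacks", {
  # one 100 x 100 mm square at t = 5 mm -> 50 ml
  est <- planimetry_volume(square_contours(100, 5))
  expect_equal(est$skv_ml, 50)
  expect_identical(est$method, "polyline_planimetry")
  # intermediates recompute the estimate exactly
  expect_equal(sum(est$intermediates$areas_mm2) *
                 est$intermediates$slice_thickness / 1000, est$skv_ml)
})

test_that("planimetry stays inside the serial-sectioning error bounds", {
  # MR sectioning of the 50/50/75 ellipsoid: |error| below 0.26%
  cs <- contour_stack(ell5075(), geo_mr_coarse())
  expect_equal(planimetry_volume(cs)$skv_ml, 785.3982, tolerance = 2.6e-3)
  # CT sectioning of the sphere: |error| below 0.2%
  cs2 <- contour_stack(sphere60(), geo_ct_coarse())
  expect_equal(planimetry_volume(cs2)$skv_ml, 904.7787, tolerance = 2e-3)
})

test_that("planimetry refuses self-intersecting polygons", {
  bow <- square_contours(100, 5)
  bow$slices[[1]]$vertices <- rbind(c(-50, -50), c(50, 50),
                                    c(50, -50), c(-50, 50))
  expect_error(planimetry_volume(bow), "self-intersecting")
})

test_that("stereology is exact on a lattice-aligned box", {
  mask <- box_mask(half = 80, spacing = 2, thickness = 16,
                   matrix_size = 100L, n_slices = 10L)
  grid <- stereology_grid(mask$geometry, spacing = c(16, 16),
                          grid_slice_thickness = 16, offset = c(0, 0, 0))
  est <- stereology_volume(mask, grid)
  expect_identical(est$intermediates$point_count, 1000L)
  expect_equal(est$skv_ml, 4096)  # 160^3 mm^3 box
})

test_that("stereology is unbiased over random grid offsets and seed-deterministic", {
  mask <- voxelize(sphere60(), geo_ct_coarse())
  vals <- vapply(1:500, function(s)
    stereology_volume(mask, stereology_grid(mask$geometry, seed = s))$skv_ml,
    numeric(1))
  true <- analytic_volume(ellipsoid_spec(c(60, 60, 60)))
  expect_lt(abs(mean(vals) - true) / true, 0.01)   # Cavalieri property
  rel_sd <- sd(vals) / mean(vals)
  expect_gt(rel_sd, 0.01)
  expect_lt(rel_sd, 0.06)
  g1 <- stereology_grid(mask$geometry, seed = 7)
  g2 <- stereology_grid(mask$geometry, seed = 7)
  expect_identical(stereology_volume(mask, g1)$intermediates$point_count,
                   stereology_volume(mask, g2)$intermediates$point_count)
})

test_that("stereology warns and returns zero when the grid misses the object", {
  tiny <- voxelize(kidney_phantom(ellipsoid_spec(c(4, 4, 4))),
                   geo_ct_coarse(spacing = 1, matrix_size = 64L))
  grid <- stereology_grid(tiny$geometry, spacing = c(60, 60),
                          grid_slice_thickness = 15, offset = c(25, 25, 0))
  expect_warning(est <- stereology_volume(tiny, grid), "estimate is 0")
  expect_equal(est$skv_ml, 0)
})

test_that("mid-slice method applies area x covering slices x thickness x factor", {
  sq <- square_contours(100, 5)
  est <- midslice_volume(sq, side = "right")
  expect_equal(est$skv_ml, 100 * 100 * 1 * 5 * 0.637 / 1000)
  expect_equal(midslice_volume(sq, side = "left")$skv_ml,
               100 * 100 * 1 * 5 * 0.624 / 1000)
})

test_that("mid-slice with factor 2/3 is asymptotically exact for ellipsoids", {
  g_fine <- imaging_geometry("MR", slice_thickness = 0.5,
                             in_plane_spacing = 2, matrix_size = 160L)
  cs <- contour_stack(ell5075(), g_fine)
  est <- midslice_volume(cs, side = "right")
  k <- est$intermediates$factor
  v23 <- est$skv_ml / k * (2 / 3)
  expect_equal(v23, 785.3982, tolerance = 0.015)
  # and the empirical factors are biased low by k/(2/3) - 1
  expect_equal(est$skv_ml / v23 - 1, 0.637 / (2 / 3) - 1, tolerance = 1e-9)
  left <- midslice_volume(cs, side = "left")
  expect_equal(left$skv_ml / (left$skv_ml / 0.624 * (2 / 3)) - 1,
               0.624 / (2 / 3) - 1, tolerance = 1e-9)
})

test_that("caliper measurements recover the extents of an axis-aligned ellipsoid", {
  mask <- voxelize(ell5075(), geo_ct_coarse())
  ax <- measure_axes(mask)
  expect_equal(ax$length_coronal, 150, tolerance = 0.04)
  expect_equal(ax$length_sagittal, 150, tolerance = 0.04)
  expect_equal(ax$width, 100, tolerance = 0.03)
  expect_equal(ax$depth, 100, tolerance = 0.03)
})

test_that("length from the coronal silhouette is rotation-stable (max chord)", {
  rot <- ell5075(rotation = c(0, 15 * pi / 180, 0))  # 15 deg about AP
  mask <- voxelize(rot, geo_ct_coarse())
  ax <- measure_axes(mask)
  # projection onto the coronal plane keeps the full 150 mm diameter
  expect_equal(ax$length_coronal, 150, tolerance = 0.05)
  expect_gte(ax$width, 100 * 0.97)
  expect_equal(kidney_length(mask), 15, tolerance = 0.05)
})

test_that("a single-voxel mask yields one-voxel extents", {
  g <- geo_ct_coarse(spacing = 1, matrix_size = 16L)
  vox <- array(FALSE, dim = c(16, 16, 1))
  vox[8, 8, 1] <- TRUE
  mask <- structure(list(geometry = g, voxels = vox, slice_index = 0L,
                         slice_z = 2.5), class = "kv_mask")
  ax <- measure_axes(mask)
  expect_equal(ax$width, 1)
  expect_equal(ax$depth, 1)
  expect_equal(ax$length_coronal, g$slice_thickness)  # voxel spans the slab
})

test_that("ellipsoid caliper formula matches hand values and rejects bad axes", {
  ax <- list(length_coronal = 150, length_sagittal = 150,
             width = 100, depth = 100)
  expect_equal(ellipsoid_method_volume(ax, "right")$skv_ml, 785.3982,
               tolerance = 1e-6)
  ax$length_sagittal <- 140
  expect_equal(ellipsoid_method_volume(ax, "left")$skv_ml, 759.2182,
               tolerance = 1e-6)
  ax$width <- -1
  expect_error(ellipsoid_method_volume(ax), "positive")
})

test_that("ellipsoid-method error grows with bump amplitude", {
  g <- geo_ct_coarse(spacing = 2)
  amps <- c(0, 2, 4, 6, 8)  # mm, on a 50/50/75 ellipsoid base
  errs <- vapply(amps, function(a) {
    b <- if (a == 0) NULL else
      data.frame(dx = c(1, 0, -0.5), dy = c(0.2, 1, 0.5),
                 dz = c(0.1, -0.4, 1), radius = 25, amplitude = a)
    ph <- kidney_phantom(ellipsoid_spec(c(50, 50, 75)), b)
    est <- ellipsoid_method_volume(measure_axes(voxelize(ph, g)), ph$side)
    abs(100 * (est$skv_ml - oracle_volume(ph)) / oracle_volume(ph))
  }, numeric(1))
  expect_gt(cor(amps, errs, method = "spearman"), 0)
})

test_that("kidney length tracks the longest silhouette chord in cm", {
  expect_equal(kidney_length(voxelize(sphere60(), geo_ct_coarse())), 12,
               tolerance = 0.05)
  co <- generate_cohort(12, c(600, 5000), geo_mr_coarse(3), seed = 31)
  lens <- vapply(co, function(p)
    kidney_length(voxelize(p, geo_mr_coarse(3))), numeric(1))
  r <- pearson(lens, attr(co, "oracle_ml"))
  expect_gt(r$r, 0.85)
  expect_lt(r$p, 0.01)
})
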