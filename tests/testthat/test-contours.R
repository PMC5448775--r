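test_that("a central slice of a sphere yields the circle area", {
  # shift the stack so one slice mid-plane passes through the centre
  g <- geo_ct_coarse(offset = -2.5)
  cs <- contour_stack(sphere60(), g)
  z <- vapply(cs$slices, `[[`, numeric(1), "z_mm")
  central <- cs$slices[[which.min(abs(z))]]
  expect_equal(central$z_mm, 0)
  expect_equal(polygon_area(central$vertices), pi * 60^2,
               tolerance = 1e-3)  # within 0.1% (chord deficit at 128 verts)
})

test_that("tangent and empty slice planes are omitted", {
  # mid-planes at ..., 55, 60 (tangent), 65: tangent/exterior slices dropped
  g <- geo_ct_coarse(offset = -2.5)
  cs <- contour_stack(sphere60(), g)
  z <- vapply(cs$slices, `[[`, numeric(1), "z_mm")
  expect_true(all(abs(z) < 60))
  # a flat phantom sitting between two mid-planes meets no slice at all
  flat <- kidney_phantom(ellipsoid_spec(c(10, 10, 2), center = c(0, 0, 5)))
  expect_error(contour_stack(flat, geo_ct_coarse(1, 64L)), "slice")
})

test_that("per-slice areas match the analytic ellipsoid cross-sections", {
  g <- geo_mr_coarse()  # coronal: slices stacked along the AP axis
  cs <- contour_stack(ell5075(), g)
  for (sl in cs$slices) {
    a_true <- pi * 50 * 75 * (1 - sl$z_mm^2 / 50^2)
    if (a_true < 200) next  # skip sliver caps where chord error dominates
    expect_equal(polygon_area(sl$vertices), a_true, tolerance = 2e-3)
  }
  # planimetric integral of the areas lands within 1% of the true volume
  expect_equal(planimetry_volume(cs)$skv_ml, 785.3982, tolerance = 0.01)
})

test_that("contour areas integrate to the oracle volume for bumpy phantoms", {
  co <- generate_cohort(3, c(800, 4000), geo_mr_coarse(3), seed = 21)
  for (i in seq_along(co)) {
    v <- planimetry_volume(contour_stack(co[[i]], geo_mr_coarse(3)))$skv_ml
    expect_equal(v, attr(co, "oracle_ml")[i], tolerance = 0.01)
  }
})

test_that("rater noise is an exact identity when switched off and is seed-deterministic", {
  cs <- contour_stack(sphere60(), geo_ct_coarse())
  off <- rater_noise_model(boundary_sd = 0, slice_miss_prob = 0, seed = 1)
  expect_identical(apply_rater_noise(cs, off), cs)
  m <- rater_noise_model(1.5, 20, 0.5, 0.1, seed = 42)
  expect_identical(apply_rater_noise(cs, m), apply_rater_noise(cs, m))
  expect_error(rater_noise_model(-1), "invalid")
})

test_that("rater noise is volume-preserving in expectation with realistic spread", {
  cs <- contour_stack(sphere60(), geo_ct_coarse())
  reps <- vapply(1:200, function(s) {
    m <- rater_noise_model(boundary_sd = 1, slice_miss_prob = 0, seed = s)
    planimetry_volume(apply_rater_noise(cs, m))$skv_ml
  }, numeric(1))
  true <- analytic_volume(ellipsoid_spec(c(60, 60, 60)))
  expect_lt(abs(mean(reps) - true) / true, 0.005)  # zero-mean contract
  cv <- 100 * sd(reps) / mean(reps)
  expect_gt(cv, 0.5)  # duplicate-tracing spread of realistic magnitude
  expect_lt(cv, 3)
})

test_that("caliper noise is mean-one, deterministic, and off at cv = 0", {
  ax <- structure(list(length_coronal = 150, length_sagittal = 148,
                       width = 100, depth = 95), class = "kv_axes")
  m0 <- rater_noise_model(caliper_cv = 0, seed = 5)
  expect_identical(apply_caliper_noise(ax, m0), ax)
  m <- rater_noise_model(caliper_cv = 0.05, seed = 5)
  expect_identical(apply_caliper_noise(ax, m), apply_caliper_noise(ax, m))
  ls <- vapply(1:500, function(s) {
    apply_caliper_noise(ax, rater_noise_model(caliper_cv = 0.05,
                                              seed = s))$length_coronal
  }, numeric(1))
  expect_equal(mean(ls), 150, tolerance = 0.01)
  expect_equal(sd(ls) / mean(ls), 0.05, tolerance = 0.2)
})

test_that("rasterised contours agree with direct voxelization", {
  g <- geo_ct_coarse()
  cs <- contour_stack(sphere60(), g)
  v_raster <- mask_volume(contours_to_mask(cs))
  v_direct <- mask_volume(voxelize(sphere60(), g))
  expect_equal(v_raster, v_direct, tolerance = 0.005)
})
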