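test_that("closed-form ellipsoid volume matches hand-computed references", {
  expect_equal(analytic_volume(ellipsoid_spec(c(10, 10, 10))), 4.18879,
               tolerance = 1e-5)
  expect_equal(analytic_volume(ellipsoid_spec(c(50, 50, 75))), 785.3982,
               tolerance = 1e-6)
  # (4/3) * pi * 110 * 65 * 55 / 1000, frozen from the closed form
  expect_equal(analytic_volume(ellipsoid_spec(c(110, 65, 55))), 1647.2417,
               tolerance = 1e-6)
  expect_error(ellipsoid_spec(c(-1, 10, 10)), "positive")
})

test_that("quadrature oracle reduces to closed forms", {
  # no bumps: exact ellipsoid
  expect_identical(oracle_volume(ell5075()),
                   analytic_volume(ellipsoid_spec(c(50, 50, 75))))
  # superellipsoid closed form vs quadrature (forced via zero-amp bump)
  ph_cf <- kidney_phantom(ellipsoid_spec(c(40, 50, 80)), fullness = 2.5)
  ph_q <- kidney_phantom(ellipsoid_spec(c(40, 50, 80)),
                         data.frame(dx = 1, dy = 0, dz = 0,
                                    radius = 20, amplitude = 0),
                         fullness = 2.5)
  expect_equal(oracle_volume(ph_q), oracle_volume(ph_cf), tolerance = 1e-4)
  # bumpy oracle reproducible under quadrature refinement (< 0.1%)
  bump <- data.frame(dx = c(1, 0), dy = c(0.3, 1), dz = c(0, 0.5),
                     radius = c(25, 30), amplitude = c(5, 7))
  phb <- kidney_phantom(ellipsoid_spec(c(50, 50, 75)), bump)
  expect_equal(oracle_volume(phb, 128, 256), oracle_volume(phb, 256, 512),
               tolerance = 1e-3)
})

test_that("voxelization converges to the analytic volume", {
  true <- analytic_volume(ellipsoid_spec(c(60, 60, 60)))
  # average |error| over three slice phases per refinement level, so the
  # expectation (not one lucky alignment) is what the ladder compares
  errs <- sapply(c(4, 2, 1), function(sp) {
    mean(sapply(c(0, 1.3, 2.7), function(off) {
      g <- imaging_geometry("CT", in_plane_spacing = sp,
                            matrix_size = as.integer(ceiling(140 / sp)),
                            origin_offset = off)
      abs(mask_volume(voxelize(sphere60(), g)) - true) / true
    }))
  })
  expect_lt(errs[3], 0.005)        # 1 mm lattice within 0.5%
  expect_lt(errs[2], 0.02)
  expect_lt(errs[1], 0.05)
  expect_lt(errs[3], errs[1])      # refinement improves accuracy
})

test_that("voxelize rejects phantoms outside the field of view and honours subsampling", {
  g <- imaging_geometry("CT", in_plane_spacing = 1, matrix_size = 64L)
  expect_error(voxelize(sphere60(), g), "field of view")
  far <- kidney_phantom(ellipsoid_spec(c(20, 20, 20), center = c(500, 0, 0)))
  expect_error(voxelize(far, g), "field of view")
  # subsample changes only boundary voxels: volumes stay close
  gs <- imaging_geometry("CT", in_plane_spacing = 2, matrix_size = 48L)
  ph <- kidney_phantom(ellipsoid_spec(c(40, 40, 40)))
  v1 <- mask_volume(voxelize(ph, gs, subsample = 1))
  v3 <- mask_volume(voxelize(ph, gs, subsample = 3))
  true <- analytic_volume(ellipsoid_spec(c(40, 40, 40)))
  expect_lt(abs(v1 - v3) / true, 0.02)
})

test_that("cohort generation is reproducible, in range, and alternates sides", {
  g <- geo_mr_coarse(spacing = 3)
  co <- generate_cohort(10, c(600, 6600), g, seed = 11)
  or <- attr(co, "oracle_ml")
  expect_length(co, 10)
  expect_true(all(or >= 600 - 1e-3 & or <= 6600 + 1e-3))
  expect_identical(vapply(co, `[[`, character(1), "side"),
                   rep(c("right", "left"), 5))
  co2 <- generate_cohort(10, c(600, 6600), g, seed = 11)
  expect_equal(co, co2)
  one <- generate_cohort(1, c(800, 900), g, seed = 3)
  expect_identical(one[[1]]$side, "right")
  expect_error(generate_cohort(2, c(-5, 10), g), "positive")
  expect_error(generate_cohort(2, c(5e5, 6e5), geo_ct_coarse(1, 64L)),
               "field of view")
})

test_that("cohort oracle volumes hit their targets after joint rescaling", {
  co <- generate_cohort(6, c(700, 3000), geo_mr_coarse(3), seed = 4)
  or <- attr(co, "oracle_ml")
  # second-pass joint rescale makes oracle == target to quadrature accuracy
  expect_equal(sort(or), seq(700, 3000, length.out = 6), tolerance = 1e-3)
})
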