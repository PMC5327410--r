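test_that("hole rates respond to composition, temperature and saturation", {
  k <- hole_rate_coefficients

  # zero-oil baseline is the documented constant
  r0 <- hole_rate_model(40, 0)
  expect_equal(r0$lambda_small, unname(exp(k["a0"])))

  # charring at 300 degC halves the small-hole rate exactly
  r275 <- hole_rate_model(33.9, 23.6, 275)
  r300 <- hole_rate_model(33.9, 23.6, 300)
  expect_equal(r300$lambda_small, 0.5 * r275$lambda_small)
  expect_equal(r300$lambda_medium, r275$lambda_medium)
  expect_equal(r300$lambda_large, r275$lambda_large)

  # cultivar contrasts: more small holes with more oil, more large with
  # more protein
  expect_gt(hole_rate_model(33.9, 23.6)$lambda_small,
            hole_rate_model(48.7, 19.2)$lambda_small)
  expect_gt(hole_rate_model(48.7, 19.2)$lambda_large,
            hole_rate_model(33.9, 23.6)$lambda_large)

  # saturation kills the small and medium populations
  rs <- hole_rate_model(40, 20, water_saturated = TRUE)
  expect_identical(rs$lambda_small, 0)
  expect_identical(rs$lambda_medium, 0)
  expect_gt(rs$lambda_large, 0)

  expect_error(hole_rate_model(120, 10), class = "charvoid_validation_error")
  expect_error(hole_rate_model(40, -5), class = "charvoid_validation_error")
  expect_error(hole_rate_model(80, 40), class = "charvoid_validation_error")
  expect_error(hole_rate_model(40, 20, char_temp = 280),
               class = "charvoid_validation_error")
})

test_that("small-hole rate is monotone in oil, large in protein, on a grid", {
  ps <- seq(20, 60, length.out = 10)
  os <- seq(5, 30, length.out = 10)
  for (p in ps) {
    lam <- vapply(os, function(o) hole_rate_model(p, o)$lambda_small, 0)
    expect_true(all(diff(lam) > 0))
  }
  for (o in os) {
    lam <- vapply(ps, function(p) hole_rate_model(p, o)$lambda_large, 0)
    expect_true(all(diff(lam) > 0))
  }
})

test_that("identical specs yield bit-identical phantoms", {
  spec <- validation_phantom_spec(rng_seed = 5L)
  a <- generate_seed_phantom(spec)
  b <- generate_seed_phantom(spec)
  expect_identical(a$volume, b$volume)
  expect_identical(a$ground_truth$holes, b$ground_truth$holes)
  t1 <- simulate_hole_table(phantom_spec(33.9, 23.6, rng_seed = 9L))
  t2 <- simulate_hole_table(phantom_spec(33.9, 23.6, rng_seed = 9L))
  expect_identical(t1$holes, t2$holes)
})

test_that("zero rates and no cracks give a solid ellipsoid", {
  spec <- phantom_spec(40, 20, semi_axes = c(0.3, 0.25, 0.2), voxel_size = 10,
                       rate_override = list(lambda_small = 0,
                                            lambda_medium = 0,
                                            lambda_large = 0),
                       rng_seed = 2L)
  ph <- generate_seed_phantom(spec)
  expect_identical(nrow(ph$ground_truth$holes), 0L)
  # strictly two intensity levels and the foreground is one ellipsoid
  expect_setequal(unique(as.vector(ph$volume)), c(0, spec$char_intensity))
  mask <- ph$volume > 0
  expect_equal(max(label_components(mask, 26L)), 1L)
  # no enclosed cavities
  expect_equal(sum(mask), sum(segment_seed(ph$volume)$envelope))
})

test_that("water-saturated phantoms have no holes below 1e-5 and a 1.4x envelope", {
  spec_dry <- phantom_spec(40, 20, rng_seed = 3L)
  spec_wet <- phantom_spec(40, 20, water_saturated = TRUE, rng_seed = 3L)
  expect_equal(envelope_volume_mm3(spec_wet),
               envelope_volume_mm3(spec_dry) * 1.4^3)
  for (s in 1:5) {
    tab <- simulate_hole_table(phantom_spec(40, 20, water_saturated = TRUE,
                                            rng_seed = s))
    holes <- tab$holes[tab$holes$class == "hole", ]
    expect_true(all(holes$v >= 1e-5))
  }
})

test_that("ground-truth category counts are Poisson with the modelled mean", {
  spec_base <- phantom_spec(33.9, 23.6)
  lam <- hole_rate_model(33.9, 23.6)
  n_rep <- 200
  counts <- vapply(seq_len(n_rep), function(i) {
    tab <- simulate_hole_table(phantom_spec(33.9, 23.6, rng_seed = 5000L + i))
    sum(tab$holes$category == "Small", na.rm = TRUE)
  }, 0)
  se <- sqrt(lam$lambda_small / n_rep)
  expect_lt(abs(mean(counts) - lam$lambda_small), 3 * se)
})

test_that("ground-truth holes lie strictly inside the envelope", {
  spec <- validation_phantom_spec(n_holes = 15, crack_count = 2, rng_seed = 8L)
  ph <- generate_seed_phantom(spec)
  ax_vox <- spec$semi_axes * 1000 / spec$voxel_size
  centre <- (dim(ph$volume) - 1) / 2
  gt <- ph$ground_truth$holes
  holes <- gt[gt$class == "hole", ]
  r <- pmax(holes$a_um, holes$b_um, holes$c_um) / spec$voxel_size
  frac <- ((holes$center_z - centre[1]) / (ax_vox[1] - r))^2 +
    ((holes$center_y - centre[2]) / (ax_vox[2] - r))^2 +
    ((holes$center_x - centre[3]) / (ax_vox[3] - r))^2
  expect_true(all(frac < 1))
})

test_that("voxelized ground-truth hole volumes match the analytic ellipsoid", {
  # resolvable voids (semi-axes >= 3 voxels): voxel count x voxel volume
  # within 10% of (4/3) pi a b c
  spec <- validation_phantom_spec(n_holes = 10, crack_count = 0, rng_seed = 4L)
  ph <- generate_seed_phantom(spec)
  mask <- segment_seed(ph$volume)
  comp <- match_components(extract_void_components(mask),
                           ph$ground_truth$holes, spec$voxel_size)
  matched <- comp[!is.na(comp$gt_index), ]
  expect_gt(nrow(matched), 0)
  truth <- ph$ground_truth$holes$volume_mm3[matched$gt_index]
  expect_true(all(abs(matched$volume_mm3 - truth) / truth < 0.10))
})

test_that("impossible geometries raise a geometry error", {
  spec <- phantom_spec(40, 20, semi_axes = c(0.2, 0.2, 0.2), voxel_size = 10,
                       rate_override = list(lambda_small = 0,
                                            lambda_medium = 0,
                                            lambda_large = 3),
                       hole_radius_um = list(Large = c(400, 500)),
                       rng_seed = 1L)
  expect_error(generate_seed_phantom(spec), class = "charvoid_geometry_error")
})
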