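test_that("component labeling matches a brute-force flood fill", {
  withr::with_seed(31L, {
    for (rep in 1:4) {
      d <- sample(8:20, 3, replace = TRUE)
      mask <- array(runif(prod(d)) < 0.35, d)
      for (conn in c(6L, 26L)) {
        expect_true(same_partition(label_components(mask, conn),
                                   flood_fill_labels(mask, conn)))
      }
    }
    # and one dense mask where components merge
    mask <- array(runif(27000) < 0.6, c(30, 30, 30))
    expect_true(same_partition(label_components(mask, 6L),
                               flood_fill_labels(mask, 6L)))
  })
})

test_that("envelope volume of a solid ellipsoid is within 2% of analytic", {
  v <- make_ellipsoid_volume(c(40, 30, 30))
  mask <- segment_seed(v, voxel_size = 10)
  voxel_mm3 <- 1e-6
  analytic <- ellipsoid_voxels(c(40, 30, 30)) * voxel_mm3
  expect_lt(abs(mask$envelope_volume_mm3 - analytic) / analytic, 0.02)
  expect_equal(mask$envelope_volume_mm3, mask$material_volume_mm3)
})

test_that("segmentation keeps the largest object and rejects empty volumes", {
  v <- array(0, c(30, 30, 30))
  v[5:12, 5:12, 5:12] <- 1       # 8^3 block
  v[18:22, 18:22, 18:22] <- 1    # 5^3 block
  mask <- segment_seed(v, threshold = 0.5, voxel_size = 10)
  expect_equal(sum(mask$material), 8^3)
  expect_error(segment_seed(array(0, c(8, 8, 8)), threshold = 0.5,
                            voxel_size = 10),
               class = "charvoid_no_seed")
})

test_that("interior voids are recovered with analytic volumes", {
  v <- make_ellipsoid_volume(c(34, 30, 30), margin = 3)
  centre <- attr(v, "centre") + 1
  offsets <- as.matrix(expand.grid(z = c(-15, 0, 15), y = c(-12, 12),
                                   x = c(-12, 12)))
  radii <- rep(c(3, 4, 5), length.out = nrow(offsets))
  for (i in seq_len(nrow(offsets))) {
    v <- carve_void(v, centre + offsets[i, ], rep(radii[i], 3))
  }
  mask <- segment_seed(v, voxel_size = 10)
  comp <- extract_void_components(mask)
  expect_equal(nrow(comp), nrow(offsets))
  # match components to carved spheres by centroid and compare volumes
  for (i in seq_len(nrow(offsets))) {
    ctr <- centre + offsets[i, ] - 1
    d <- sqrt((comp$centroid_z - ctr[1])^2 + (comp$centroid_y - ctr[2])^2 +
                (comp$centroid_x - ctr[3])^2)
    j <- which.min(d)
    expect_lt(d[j], 1)
    analytic <- ellipsoid_voxels(rep(radii[i], 3)) * 1e-6
    expect_lt(abs(comp$volume_mm3[j] - analytic) / analytic, 0.10)
  }
  # solid seed: empty component table
  solid <- make_ellipsoid_volume(c(15, 12, 12))
  expect_equal(nrow(extract_void_components(
    segment_seed(solid, voxel_size = 10))), 0L)
})

test_that("void volumes and material partition the envelope exactly", {
  spec <- validation_phantom_spec(rng_seed = 21L)
  ph <- generate_seed_phantom(spec)
  mask <- segment_seed(ph$volume)
  comp <- extract_void_components(mask)
  voxel_mm3 <- prod(mask$voxel_size) * 1e-9
  expect_equal(sum(comp$voxel_count) * voxel_mm3 + mask$material_volume_mm3,
               mask$envelope_volume_mm3)
})

test_that("a void channel opening to the background is flagged exterior", {
  v <- make_ellipsoid_volume(c(20, 16, 16), margin = 4)
  centre <- attr(v, "centre") + 1
  v <- carve_void(v, centre, c(4, 4, 4))
  # 1-voxel-wide channel from the cavity out through the +x surface
  v[centre[1], centre[2], centre[3]:dim(v)[3]] <- 0
  mask <- segment_seed(v, voxel_size = 10)
  comp <- extract_void_components(mask)
  expect_equal(nrow(comp), 1L)
  expect_true(comp$touches_exterior[1])

  # the same cavity without the channel is interior
  v2 <- carve_void(make_ellipsoid_volume(c(20, 16, 16), margin = 4),
                   centre, c(4, 4, 4))
  comp2 <- extract_void_components(segment_seed(v2, voxel_size = 10))
  expect_false(comp2$touches_exterior[1])
})

test_that("classification applies the exclusion rules in order", {
  rules <- classifier_rules()
  base <- tibble::tibble(
    label = 1L, voxel_count = 500L, volume_mm3 = 5e-4,
    centroid_z = 0, centroid_y = 0, centroid_x = 0,
    a_um = 50, b_um = 45, c_um = 40, planarity = 0.8,
    touches_exterior = FALSE
  )
  klass_of <- function(...) {
    row <- dplyr::mutate(base, ...)
    classify_components(row, rules, envelope_volume_mm3 = 0.4)$klass
  }
  expect_equal(klass_of(), "hole")
  expect_equal(klass_of(voxel_count = 2L), "outlier")
  expect_equal(klass_of(volume_mm3 = 0.03), "break")         # > 5% of 0.4
  expect_equal(klass_of(touches_exterior = TRUE, planarity = 0.2), "break")
  expect_equal(klass_of(planarity = 0.05), "crack")
  expect_equal(klass_of(touches_exterior = TRUE, planarity = 0.8), "hole")
})

test_that("moment-tensor planarity separates plates from spheres", {
  # voxel plate with semi-axes (20, 20, 1): planarity far below tau_crack
  v <- make_ellipsoid_volume(c(30, 30, 10), margin = 3)
  centre <- attr(v, "centre") + 1
  d <- dim(v)
  ell <- outer(((seq_len(d[1]) - centre[1]) / 20)^2,
               ((seq_len(d[2]) - centre[2]) / 20)^2, `+`)
  plate <- array(FALSE, d)
  plate[, , centre[3]][ell <= 1] <- TRUE
  v[plate] <- 0
  comp <- classify_components(
    extract_void_components(segment_seed(v, voxel_size = 10)))
  expect_equal(nrow(comp), 1L)
  expect_lt(comp$planarity[1], 0.15)
  expect_equal(comp$klass[1], "crack")

  # sphere of radius 5: planarity near 1, classified hole
  v2 <- make_ellipsoid_volume(c(18, 15, 15))
  v2 <- carve_void(v2, attr(v2, "centre") + 1, c(5, 5, 5))
  comp2 <- classify_components(
    extract_void_components(segment_seed(v2, voxel_size = 10)))
  expect_gt(comp2$planarity[1], 0.8)
  expect_equal(comp2$klass[1], "hole")
})

test_that("crack contamination handles the edge cases", {
  comp <- tibble::tibble(klass = c("hole", "hole", "crack"),
                         true_class = c("hole", "hole", "crack"))
  expect_equal(crack_contamination(comp), 0)
  comp_all_bad <- tibble::tibble(klass = c("hole", "hole"),
                                 true_class = c("crack", "crack"))
  expect_equal(crack_contamination(comp_all_bad), 1)
  none <- tibble::tibble(klass = "crack", true_class = "crack")
  expect_true(is.na(crack_contamination(none)))
})

test_that("anisotropic voxels scale the moment tensor per axis", {
  # a sphere in physical units sampled on 2:1 anisotropic voxels must
  # still look spherical (planarity ~ 1) when the scaling is applied
  vs <- c(20, 10, 10)  # um/voxel; z twice as coarse
  d <- c(41, 81, 81)
  ctr <- (d + 1) / 2
  v <- array(0, d)
  # seed ellipsoid 350 um semi-axis in every physical direction
  seed2 <- outer(outer((((seq_len(d[1]) - ctr[1]) * vs[1]) / 350)^2,
                       (((seq_len(d[2]) - ctr[2]) * vs[2]) / 350)^2, `+`),
                 (((seq_len(d[3]) - ctr[3]) * vs[3]) / 350)^2, `+`)
  v[seed2 <= 1] <- 1
  # carve a 100 um sphere at the centre
  hole2 <- outer(outer((((seq_len(d[1]) - ctr[1]) * vs[1]) / 100)^2,
                       (((seq_len(d[2]) - ctr[2]) * vs[2]) / 100)^2, `+`),
                 (((seq_len(d[3]) - ctr[3]) * vs[3]) / 100)^2, `+`)
  v[hole2 <= 1] <- 0
  comp <- extract_void_components(segment_seed(v, voxel_size = vs))
  expect_equal(nrow(comp), 1L)
  expect_gt(comp$planarity[1], 0.9)
  expect_lt(abs(comp$a_um[1] - 100) / 100, 0.1)
})
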