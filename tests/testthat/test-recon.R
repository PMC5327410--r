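test_that("effective pixel size is detector pixel over magnification", {
  expect_equal(effective_pixel(6.5, 2), 3.25)
  expect_equal(effective_pixel(6.5, 4), 1.625)
  expect_equal(effective_pixel(11, 1), 11)
  expect_error(effective_pixel(-1, 2), class = "charvoid_validation_error")
  expect_error(effective_pixel(6.5, 0), class = "charvoid_validation_error")
})

fake_sinogram <- function(I, F = 100, D = 0) {
  structure(list(
    projections = array(I, c(1, 2, 3)),
    flats = array(F, c(2, 2, 3)),
    darks = array(D, c(2, 2, 3)),
    angles = 0, voxel_size_um = 10
  ), class = "sinogram_set")
}

test_that("flat/dark correction reproduces closed-form optical depths", {
  expect_equal(max(abs(correct_projections(fake_sinogram(100))$projections)), 0)
  # I - Dbar = (Fbar - Dbar)/e -> exactly 1
  s <- fake_sinogram(10 + 90 / exp(1), F = 100, D = 10)
  expect_equal(correct_projections(s)$projections[1, 1, 1], 1)
  # I = 50, F = 100, D = 0 -> ln 2
  expect_equal(correct_projections(fake_sinogram(50))$projections[1, 2, 2],
               log(2), tolerance = 1e-12)
  # monotone decreasing in I
  p_vals <- vapply(c(90, 70, 50, 30), function(I) {
    correct_projections(fake_sinogram(I))$projections[1, 1, 1]
  }, 0)
  expect_true(all(diff(p_vals) > 0))
  # flat not exceeding dark is a data error naming the pixel
  expect_error(correct_projections(fake_sinogram(50, F = 5, D = 10)),
               class = "charvoid_data_error")
  # floor keeps output finite at zero transmittance
  expect_true(is.finite(
    correct_projections(fake_sinogram(0))$projections[1, 1, 1]))
})

test_that("projection simulation matches analytic line integrals", {
  # zero-attenuation volume, noiseless: every projection equals the flat
  vol0 <- array(0, c(2, 8, 8))
  attr(vol0, "voxel_size_um") <- 10
  s <- simulate_projections(vol0, c(0, pi / 4, pi / 2), flux = 500,
                            noise = FALSE, dark_level = 7)
  expect_equal(max(abs(s$projections - (500 + 7))), 0)
  expect_equal(dim(s$projections)[1], 3L)

  # single voxel of attenuation mu on the rotation centre: optical depth
  # is mu * voxel_size for an axis-aligned ray
  n <- 17
  vol <- array(0, c(1, n, n))
  vol[1, (n + 1) / 2, (n + 1) / 2] <- 0.8
  attr(vol, "voxel_size_um") <- 50
  s1 <- simulate_projections(vol, 0, flux = 1000, noise = FALSE,
                             dark_level = 0)
  depth <- -log(s1$projections[1, 1, ] / 1000)
  expect_equal(max(depth), 0.8 * 50 / 1000, tolerance = 1e-8)
  expect_equal(sum(depth), 0.8 * 50 / 1000, tolerance = 1e-8)

  expect_error(simulate_projections(vol0, numeric(0)),
               class = "charvoid_validation_error")
  expect_error(simulate_projections(vol0, c(0, 0.1), flux = 0),
               class = "charvoid_validation_error")
  expect_error(simulate_projections(vol0, c(0.5, 0.1)),
               class = "charvoid_validation_error")
})

test_that("FBP is linear, zero-preserving and validates its inputs", {
  angles <- seq(0, pi, length.out = 31)[1:30]
  p0 <- structure(list(projections = array(0, c(30, 1, 32)),
                       angles = angles, voxel_size_um = 50),
                  class = "attenuation_projections")
  expect_equal(max(abs(fbp_reconstruct(p0))), 0)

  vol <- make_disk_volume(n = 64, radius = 20)
  s <- simulate_projections(vol, angles, flux = 1e4, noise = FALSE)
  p <- correct_projections(s)
  rec1 <- fbp_reconstruct(p)
  p2 <- p
  p2$projections <- 3 * p$projections
  expect_equal(fbp_reconstruct(p2), 3 * rec1, tolerance = 1e-12)

  bad <- p
  bad$angles <- angles[-1]
  expect_error(fbp_reconstruct(bad), class = "charvoid_validation_error")
})

test_that("FBP recovers a uniform disk within 5% and is rotation covariant", {
  mu <- 0.4
  vol <- make_disk_volume(n = 96, radius = 30, mu = mu, voxel_um = 50)
  angles <- seq(0, pi, length.out = 145)[1:144]
  s <- simulate_projections(vol, angles, flux = 1e5, noise = FALSE)
  rec <- fbp_reconstruct(correct_projections(s))
  n <- 96
  cc <- (n - 1) / 2
  interior <- outer(((1:n) - 1 - cc)^2, ((1:n) - 1 - cc)^2, `+`) <= 25^2
  expect_lt(abs(mean(rec[1, , ][interior]) - mu) / mu, 0.05)

  # centro-symmetric phantom: shifting all angles leaves the volume intact
  angles2 <- angles + pi / 288
  s2 <- simulate_projections(vol, angles2, flux = 1e5, noise = FALSE)
  rec2 <- fbp_reconstruct(correct_projections(s2))
  expect_lt(mean(abs(rec2[1, , ][interior] - rec[1, , ][interior])) / mu, 0.02)
})

test_that("simulate -> correct -> reconstruct round-trips a 3D phantom", {
  spec <- phantom_spec(40, 20, semi_axes = c(0.28, 0.24, 0.22),
                       voxel_size = 10,
                       rate_override = list(lambda_small = 0,
                                            lambda_medium = 0,
                                            lambda_large = 6),
                       hole_radius_um = list(Large = c(30, 60)),
                       rng_seed = 11L)
  ph <- generate_seed_phantom(spec)
  angles <- seq(0, pi, length.out = 91)[1:90]
  s <- simulate_projections(ph$volume, angles, flux = 2e4, rng_seed = 5L)
  rec <- fbp_reconstruct(correct_projections(s),
                         out_shape = dim(ph$volume)[2:3])
  expect_gt(cor(as.vector(rec), as.vector(ph$volume)), 0.95)
})
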