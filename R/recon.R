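#' Effective detector pixel size after lens magnification
#'
#' @param detector_pixel Physical CCD pixel size, um.
#' @param magnification Lens magnification (unitless, `> 0`).
#' @return Effective pixel size at the sample, um: `detector_pixel /
#'   magnification`. A 6.5 um CCD behind a 2x or 4x lens resolves 3.25 um
#'   or 1.625 um respectively.
#' @export
effective_pixel <- function(detector_pixel, magnification) {
  cv_assert(is.numeric(detector_pixel) && all(detector_pixel > 0),
            "charvoid_validation_error", "detector_pixel must be > 0")
  cv_assert(is.numeric(magnification) && all(magnification > 0),
            "charvoid_validation_error", "magnification must be > 0")
  detector_pixel / magnification
}

#' Simulate parallel-beam projections of a volume
#'
#' Forward-projects a 3D attenuation volume slice by slice (each z-slice is
#' projected along rays in its own plane), applies the Beer-Lambert law at
#' the given incident flux, and emits flat frames (beam on, sample out) and
#' dark frames (beam off) alongside the projections, mimicking a
#' synchrotron tomography acquisition.
#'
#' @param volume 3D array (z, y, x) of attenuation in mm^-1, with a
#'   `voxel_size_um` attribute (or pass `voxel_size_um`).
#' @param angles Projection angles in radians, strictly increasing in
#'   `[0, pi)`.
#' @param flux Incident photon count per detector pixel (`> 0`).
#' @param rng_seed Integer seed for the counting noise.
#' @param noise If `FALSE`, emit noiseless expected counts.
#' @param n_flats,n_darks Number of flat and dark frames.
#' @param dark_level Mean dark counts per pixel.
#' @param voxel_size_um Voxel size override, um.
#' @return An object of class `sinogram_set`: list with `projections`
#'   (array `n_angles x nz x ndet` of detector counts), `flats` and `darks`
#'   (arrays `k x nz x ndet`), `angles`, and `voxel_size_um`.
#' @export
simulate_projections <- function(volume, angles, flux = 1e4, rng_seed = 1L,
                                 noise = TRUE, n_flats = 5L, n_darks = 5L,
                                 dark_level = 20, voxel_size_um = NULL) {
  cv_assert(length(dim(volume)) == 3, "charvoid_validation_error",
            "volume must be a 3D array")
  cv_assert(length(angles) > 0, "charvoid_validation_error",
            "angles must be non-empty")
  cv_assert(!is.unsorted(angles, strictly = TRUE) &&
              all(angles >= 0 & angles < pi),
            "charvoid_validation_error",
            "angles must be strictly increasing in [0, pi)")
  cv_assert(is.numeric(flux) && flux > 0, "charvoid_validation_error",
            "flux must be > 0")
  vs <- voxel_size_um %||% attr(volume, "voxel_size_um")
  cv_assert(!is.null(vs) && vs > 0, "charvoid_validation_error",
            "voxel size (um) is required, via attribute or argument")

  d <- dim(volume)
  nz <- d[1]
  ndet <- max(d[2], d[3])
  na <- length(angles)
  # optical depth p = mu (mm^-1) * path (voxels) * voxel (mm)
  depth <- array(0, c(na, nz, ndet))
  for (z in seq_len(nz)) {
    depth[, z, ] <- radon_cpp(volume[z, , ], angles) * (vs / 1000)
  }
  expected <- flux * exp(-depth)

  withr::with_seed(rng_seed, {
    draw <- function(mean_arr) {
      if (noise) array(stats::rpois(length(mean_arr), mean_arr) * 1.0,
                       dim(mean_arr))
      else mean_arr
    }
    projections <- draw(expected + dark_level)
    flats <- array(0, c(n_flats, nz, ndet))
    darks <- array(0, c(n_darks, nz, ndet))
    for (k in seq_len(n_flats)) {
      flats[k, , ] <- draw(array(flux + dark_level, c(1, nz, ndet)))[1, , ]
    }
    for (k in seq_len(n_darks)) {
      darks[k, , ] <- draw(array(dark_level, c(1, nz, ndet)))[1, , ]
    }
  })

  structure(list(projections = projections, flats = flats, darks = darks,
                 angles = angles, voxel_size_um = vs),
            class = "sinogram_set")
}

#' Flat- and dark-field correction of raw projections
#'
#' Converts raw detector counts to line integrals of attenuation (optical
#' depth) using the standard normalization `p = -ln((I - Dbar) / (Fbar -
#' Dbar))`, with the flat frames `F` and dark frames `D` averaged
#' pixelwise. The transmittance is clamped below at `trans_floor` before
#' the logarithm so the output is always finite.
#'
#' @param s A `sinogram_set` from [simulate_projections()] (or a list with
#'   the same fields).
#' @param trans_floor Transmittance floor applied before the log.
#' @return An object of class `attenuation_projections`: list with
#'   `projections` (array `n_angles x nz x ndet` of optical depth),
#'   `angles`, `voxel_size_um`.
#' @export
correct_projections <- function(s, trans_floor = 1e-6) {
  cv_assert(all(c("projections", "flats", "darks", "angles") %in% names(s)),
            "charvoid_validation_error",
            "input must carry projections, flats, darks and angles")
  fbar <- colMeans(s$flats, dims = 1)
  dbar <- colMeans(s$darks, dims = 1)
  bad <- which(fbar <= dbar, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cv_stop("charvoid_data_error",
            "mean flat does not exceed mean dark at pixel (row %d, col %d)",
            bad[1, 1], bad[1, 2])
  }
  gain <- fbar - dbar
  na <- dim(s$projections)[1]
  p <- s$projections
  for (a in seq_len(na)) {
    trans <- (p[a, , ] - dbar) / gain
    p[a, , ] <- -log(pmax(trans, trans_floor))
  }
  structure(list(projections = p, angles = s$angles,
                 voxel_size_um = s$voxel_size_um),
            class = "attenuation_projections")
}

# Discrete Ram-Lak filter kernel evaluated in the Fourier domain (the
# standard spatial-domain construction, which avoids the DC bias of a
# naive |omega| ramp), optionally apodized with a Hann window.
ramp_filter_freq <- function(n, filter = c("ramlak", "hann")) {
  filter <- match.arg(filter)
  h <- numeric(n)
  h[1] <- 0.25
  k <- seq_len(n %/% 2)
  odd <- k[k %% 2 == 1]
  h[1 + odd] <- -1 / (pi * odd)^2
  h[n + 1 - odd] <- -1 / (pi * odd)^2
  H <- 2 * Re(stats::fft(h))
  if (filter == "hann") {
    f <- seq(0, n - 1) / n
    f <- pmin(f, 1 - f) * 2           # normalized |frequency| in [0, 1]
    H <- H * (0.5 * (1 + cos(pi * f)))
  }
  H
}

#' Filtered back projection reconstruction
#'
#' Slice-by-slice parallel-beam FBP: each sinogram row is ramp-filtered
#' (Ram-Lak, optionally Hann-apodized) in the Fourier domain with
#' zero-padding, then back-projected. Linear in its input.
#'
#' @param p An `attenuation_projections` object from
#'   [correct_projections()], or a list with `projections`
#'   (`n_angles x nz x ndet`), `angles`, `voxel_size_um`.
#' @param out_shape Output (ny, nx) of each slice; defaults to
#'   `c(ndet, ndet)`.
#' @param voxel_size Voxel size in um; defaults to the input's.
#' @param filter `"ramlak"` or `"hann"`.
#' @return 3D array (z, y, x) of attenuation in mm^-1 with a
#'   `voxel_size_um` attribute.
#' @export
fbp_reconstruct <- function(p, out_shape = NULL, voxel_size = NULL,
                            filter = c("ramlak", "hann")) {
  filter <- match.arg(filter)
  cv_assert(length(dim(p$projections)) == 3, "charvoid_validation_error",
            "projections must be an n_angles x nz x ndet array")
  na <- dim(p$projections)[1]
  cv_assert(length(p$angles) == na, "charvoid_validation_error",
            "angle count (%d) does not match projection count (%d)",
            length(p$angles), na)
  cv_assert(na >= 2, "charvoid_validation_error",
            "at least 2 angles are required")
  nz <- dim(p$projections)[2]
  ndet <- dim(p$projections)[3]
  vs <- voxel_size %||% p$voxel_size_um
  out_shape <- out_shape %||% c(ndet, ndet)

  npad <- max(64, 2^ceiling(log2(2 * ndet)))
  H <- ramp_filter_freq(npad, filter)
  vol <- array(0, c(nz, out_shape[1], out_shape[2]))
  for (z in seq_len(nz)) {
    sino <- p$projections[, z, , drop = TRUE]
    if (is.null(dim(sino))) sino <- matrix(sino, nrow = na)
    padded <- matrix(0, na, npad)
    padded[, seq_len(ndet)] <- sino
    filt <- t(apply(padded, 1, function(row) {
      Re(stats::fft(stats::fft(row) * H, inverse = TRUE)) / npad
    }))[, seq_len(ndet), drop = FALSE]
    vol[z, , ] <- backproject_cpp(filt, p$angles, out_shape[1], out_shape[2])
  }
  # line integrals are unitless optical depth over paths measured in
  # pixels of size vs; convert the reconstructed values to mm^-1
  vol <- vol / (vs / 1000)
  attr(vol, "voxel_size_um") <- vs
  vol
}

`%||%` <- function(a, b) if (is.null(a)) b else a
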