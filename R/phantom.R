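#' Log-linear coefficients of the composition -> hole-rate model
#'
#' Documented constants of [hole_rate_model()]. Expected per-seed hole
#' counts are log-linear in composition: `lambda_small = exp(a0 + a1 * O)`,
#' `lambda_large = exp(b0 + b1 * P)`, `lambda_medium = exp(c0 + c1 *
#' (O + P) / 2)`, with `O` and `P` the oil and protein percentages of dry
#' mass. The coefficients are fixed so that the three reference cultivars
#' (P48.7/O19.2, P42.5/O15, P33.9/O23.6) reproduce the observed orderings:
#' most Small holes for the high-oil cultivar, largest Large-category mean
#' for the high-protein cultivar, and per-seed totals of order a few
#' thousand holes.
#'
#' @format Named numeric vector with elements `a0`, `a1`, `b0`, `b1`,
#'   `c0`, `c1`.
#' @export
hole_rate_coefficients <- c(
  a0 = 5.0, a1 = 0.10,   # Small:  oil-driven
  b0 = 1.0, b1 = 0.06,   # Large:  protein-driven
  c0 = 3.0, c1 = 0.08    # Medium: mean composition
)

#' Expected hole counts per seed from composition and treatment
#'
#' Maps seed composition and charring treatment to Poisson means for the
#' number of Small, Medium and Large internal holes. The model encodes the
#' established qualitative effects: oil drives the abundance of small
#' holes, protein drives large holes, charring at 300 degC halves the
#' small-hole rate relative to 275 degC, and water saturation before
#' charring eliminates the small and medium holes entirely.
#'
#' @param protein_pct Protein content, percent of dry mass, in `[0, 100]`.
#' @param oil_pct Oil content, percent of dry mass, in `[0, 100]`.
#' @param char_temp Charring temperature in degC; one of 275 or 300.
#' @param water_saturated Logical; was the seed soaked to saturation before
#'   charring?
#' @return An object of class `hole_rates`: a list with elements
#'   `lambda_small`, `lambda_medium`, `lambda_large` (expected counts per
#'   seed, all `>= 0`).
#' @examples
#' hole_rate_model(33.9, 23.6)                  # high-oil cultivar
#' hole_rate_model(33.9, 23.6, char_temp = 300) # half the small-hole rate
#' @export
hole_rate_model <- function(protein_pct, oil_pct, char_temp = 275,
                            water_saturated = FALSE) {
  cv_assert(is.numeric(protein_pct) && length(protein_pct) == 1 &&
              is.finite(protein_pct) && protein_pct >= 0 && protein_pct <= 100,
            "charvoid_validation_error",
            "protein_pct must be a percentage in [0, 100], got %s",
            format(protein_pct))
  cv_assert(is.numeric(oil_pct) && length(oil_pct) == 1 &&
              is.finite(oil_pct) && oil_pct >= 0 && oil_pct <= 100,
            "charvoid_validation_error",
            "oil_pct must be a percentage in [0, 100], got %s", format(oil_pct))
  cv_assert(protein_pct + oil_pct <= 100, "charvoid_validation_error",
            "protein_pct + oil_pct must not exceed 100")
  cv_assert(char_temp %in% c(275, 300), "charvoid_validation_error",
            "char_temp must be 275 or 300 degC")
  cv_assert(is.logical(water_saturated) && length(water_saturated) == 1,
            "charvoid_validation_error", "water_saturated must be TRUE/FALSE")

  k <- hole_rate_coefficients
  temp_factor <- if (char_temp == 300) 0.5 else 1.0
  lam <- list(
    lambda_small  = unname(exp(k["a0"] + k["a1"] * oil_pct)) * temp_factor,
    lambda_medium = unname(exp(k["c0"] + k["c1"] * (oil_pct + protein_pct) / 2)),
    lambda_large  = unname(exp(k["b0"] + k["b1"] * protein_pct))
  )
  if (water_saturated) {
    lam$lambda_small <- 0
    lam$lambda_medium <- 0
  }
  structure(lam, class = "hole_rates")
}

#' Specification of one synthetic seed phantom
#'
#' Collects all generative parameters of a charred-seed phantom. Defaults
#' describe a large-mode soybean (5.1 x 2.5 x 2.4 mm, the printed
#' dimensions of a Longshan-period specimen) charred dry at 275 degC,
#' voxelized at 55 um so the long axis spans roughly 96 voxels.
#'
#' @param protein_pct,oil_pct Composition, percent of dry mass.
#' @param char_temp Charring temperature, 275 or 300 degC.
#' @param water_saturated Logical; soaking enlarges the seed envelope by a
#'   linear factor 1.4 and suppresses Small and Medium holes.
#' @param semi_axes Seed ellipsoid semi-axes in mm, (z, y, x) order.
#' @param voxel_size Voxel edge length in um.
#' @param crack_count Number of thin planar cracks to add.
#' @param break_flag Simulate a cotyledon-separation break (planar gap
#'   through the seed centre).
#' @param rng_seed Integer seed; the same spec always yields bit-identical
#'   output.
#' @param hole_radius_um Optional named list overriding the per-category
#'   mean-radius ranges in um, e.g. `list(Large = c(35, 80))`; categories
#'   not named keep the default decade-derived range. Intended for
#'   segmentation validation at voxel-resolvable hole sizes.
#' @param rate_override Optional `hole_rates`-like list overriding the
#'   composition-driven Poisson means.
#' @param char_intensity Attenuation assigned to char material, mm^-1.
#' @return An object of class `phantom_spec` (a named list).
#' @export
phantom_spec <- function(protein_pct, oil_pct, char_temp = 275,
                         water_saturated = FALSE,
                         semi_axes = c(2.55, 1.25, 1.2),
                         voxel_size = 55,
                         crack_count = 0L, break_flag = FALSE,
                         rng_seed = 1L,
                         hole_radius_um = NULL,
                         rate_override = NULL,
                         char_intensity = 0.5) {
  # reuse rate-model validation for the composition fields
  hole_rate_model(protein_pct, oil_pct, char_temp, water_saturated)
  cv_assert(is.numeric(semi_axes) && length(semi_axes) == 3 && all(semi_axes > 0),
            "charvoid_validation_error", "semi_axes must be 3 positive lengths (mm)")
  cv_assert(is.numeric(voxel_size) && length(voxel_size) == 1 && voxel_size > 0,
            "charvoid_validation_error", "voxel_size must be a positive length (um)")
  cv_assert(crack_count >= 0, "charvoid_validation_error", "crack_count must be >= 0")
  structure(list(
    protein_pct = protein_pct, oil_pct = oil_pct, char_temp = char_temp,
    water_saturated = water_saturated, semi_axes = as.numeric(semi_axes),
    voxel_size = voxel_size, crack_count = as.integer(crack_count),
    break_flag = isTRUE(break_flag), rng_seed = as.integer(rng_seed),
    hole_radius_um = hole_radius_um, rate_override = rate_override,
    char_intensity = char_intensity
  ), class = "phantom_spec")
}

# Effective seed semi-axes in mm after the water-saturation enlargement
# (interpreted as a linear factor 1.4).
effective_semi_axes <- function(spec) {
  if (spec$water_saturated) spec$semi_axes * 1.4 else spec$semi_axes
}

#' Analytic envelope volume of a phantom spec, mm^3
#' @param spec A [phantom_spec()].
#' @export
envelope_volume_mm3 <- function(spec) {
  ax <- effective_semi_axes(spec)
  4 / 3 * pi * prod(ax)
}

# Per-category range of the hole mean radius (um) such that a sphere of
# that radius has normalized volume inside the category's decade of the
# given envelope volume, intersected with the physical 10-500 um band in
# which such holes occur. If the intersection is empty (very small
# envelopes) the unclamped decade-derived range is used.
category_radius_range_um <- function(category, V_seed_mm3) {
  edges <- hole_category_edges[[category]]
  r_mm <- (3 * edges * V_seed_mm3 / (4 * pi))^(1 / 3)
  r_um <- r_mm * 1000
  lo <- max(r_um[1], 10)
  hi <- min(r_um[2], 500)
  if (lo >= hi) c(r_um[1], r_um[2]) else c(lo, hi)
}

# Draw one category's hole population: Poisson count, log-uniform mean
# radius, mild triaxial aspect jitter at fixed volume (so the normalized
# volume stays in the drawn decade).
sample_category_holes <- function(category, lambda, V_seed_mm3, radius_range_um) {
  n <- stats::rpois(1L, lambda)
  if (n == 0) {
    return(tibble::tibble(
      class = character(), category = character(),
      a_um = numeric(), b_um = numeric(), c_um = numeric(),
      volume_mm3 = numeric(), v = numeric()
    ))
  }
  rr <- if (is.null(radius_range_um)) {
    category_radius_range_um(category, V_seed_mm3)
  } else radius_range_um
  r_um <- exp(stats::runif(n, log(rr[1]), log(rr[2])))
  q2 <- stats::runif(n, 0.75, 1)
  q3 <- stats::runif(n, 0.75, 1)
  a <- r_um / (q2 * q3)^(1 / 3)
  vol_mm3 <- 4 / 3 * pi * (r_um / 1000)^3
  tibble::tibble(
    class = "hole", category = category,
    a_um = a, b_um = q2 * a, c_um = q3 * a,
    volume_mm3 = vol_mm3, v = vol_mm3 / V_seed_mm3
  )
}

sample_crack_population <- function(n, voxel_size) {
  if (n == 0) {
    return(tibble::tibble(
      class = character(), category = character(),
      a_um = numeric(), b_um = numeric(), c_um = numeric(),
      volume_mm3 = numeric(), v = numeric()
    ))
  }
  # thin plates: thickness/extent <= ~0.1, thick enough (>= ~3.6 voxels
  # across) that a tilted sheet stays 6-connected when voxelized
  a <- stats::runif(n, 150, 250)
  c_ax <- pmax(0.07 * a, 1.8 * voxel_size)
  a <- pmax(a, c_ax / 0.075)
  b <- 0.75 * a
  vol_mm3 <- 4 / 3 * pi * (a / 1000) * (b / 1000) * (c_ax / 1000)
  tibble::tibble(
    class = "crack", category = NA_character_,
    a_um = a, b_um = b, c_um = c_ax, volume_mm3 = vol_mm3, v = NA_real_
  )
}

# Draw the full hole/crack population for a spec (no placement). Assumes
# the RNG state is already set by the caller.
sample_hole_population <- function(spec) {
  rates <- if (!is.null(spec$rate_override)) {
    spec$rate_override
  } else {
    hole_rate_model(spec$protein_pct, spec$oil_pct, spec$char_temp,
                    spec$water_saturated)
  }
  V_seed <- envelope_volume_mm3(spec)
  rr <- function(cat) {
    if (!is.null(spec$hole_radius_um) && !is.null(spec$hole_radius_um[[cat]])) {
      spec$hole_radius_um[[cat]]
    } else NULL
  }
  holes <- dplyr::bind_rows(
    sample_category_holes("Small", rates$lambda_small, V_seed, rr("Small")),
    sample_category_holes("Medium", rates$lambda_medium, V_seed, rr("Medium")),
    sample_category_holes("Large", rates$lambda_large, V_seed, rr("Large")),
    sample_crack_population(spec$crack_count, spec$voxel_size)
  )
  list(holes = holes, rates = rates, V_seed = V_seed)
}

#' Ground-truth hole table of a phantom, without voxelization
#'
#' Draws the hole population a phantom spec implies (Poisson counts per
#' category, per-hole semi-axes and analytic volumes) without placing or
#' rendering the holes. This is the fast path used by the group-comparison
#' experiment suites, where only per-seed category counts matter; it is
#' identical in distribution to the `ground_truth$holes` table of
#' [generate_seed_phantom()].
#'
#' @param spec A [phantom_spec()].
#' @return A list with `holes` (tibble: class, category, semi-axes um,
#'   `volume_mm3`, normalized volume `v`), `rates` (the `hole_rates`
#'   used), and `envelope_volume_mm3`.
#' @export
simulate_hole_table <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$rng_seed, {
    pop <- sample_hole_population(spec)
  })
  list(holes = pop$holes, rates = pop$rates, envelope_volume_mm3 = pop$V_seed)
}

# Uniform point in the unit ball, by rejection.
runif_ball <- function() {
  repeat {
    p <- stats::runif(3, -1, 1)
    if (sum(p^2) <= 1) return(p)
  }
}

# Random rotation matrix (QR of a Gaussian matrix, sign-fixed).
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qrd)
  q * rep(sign(diag(qr.R(qrd))), each = 3)
}

#' Generate one synthetic charred-seed volume with ground truth
#'
#' Voxelizes an ellipsoidal char body containing the hole population drawn
#' from the spec's composition model. Seed material receives the spec's
#' char attenuation; holes, cracks and the optional cotyledon break are
#' carved back to background (zero) intensity. Holes are placed uniformly
#' inside the envelope with enough margin that every ground-truth hole lies
#' strictly inside it; voxel-resolvable voids are kept disjoint. Holes
#' smaller than a voxel are recorded in the ground truth but may contain no
#' voxel centre, exactly as partial-volume physics would hide them at that
#' resolution.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `seed_phantom` with elements:
#'   * `volume`: 3D numeric array (z, y, x) of attenuation (mm^-1), with
#'     attribute `voxel_size_um`;
#'   * `ground_truth`: list with `holes` (tibble adding `center_z/y/x`,
#'     0-based voxel coordinates), `envelope_volume_mm3` (analytic),
#'     `expected_counts` (the Poisson means) and `spec`.
#' @export
generate_seed_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ax_mm <- effective_semi_axes(spec)
  ax_vox <- ax_mm * 1000 / spec$voxel_size
  margin <- 3
  dims <- as.integer(ceiling(2 * ax_vox) + 2 * margin + 1)
  cv_assert(all(dims >= 2 * ax_vox + 4), "charvoid_geometry_error",
            "seed does not fit in the voxel grid with a 2-voxel margin")
  centre <- (dims - 1) / 2

  withr::with_seed(spec$rng_seed, {
    pop <- sample_hole_population(spec)
    holes <- pop$holes
    n <- nrow(holes)

    # placement: uniform in the shrunken envelope so every void fits inside;
    # voxel-resolvable voids are kept disjoint using the ellipsoid support
    # function along the line between centres (thin cracks then only claim
    # their actual extent, not a bounding sphere)
    centres <- matrix(NA_real_, n, 3)
    rot <- vector("list", n)
    if (n > 0) {
      axes_vox <- cbind(holes$a_um, holes$b_um, holes$c_um) / spec$voxel_size
      max_ax_vox <- apply(axes_vox, 1, max)
      resolvable <- max_ax_vox >= 1
      support <- function(j, u) {
        # radius of void j's ellipsoid in direction u (unit, world frame)
        sqrt(sum((axes_vox[j, ] * (u %*% rot[[j]]))^2))
      }
      placed <- integer(0)
      # biggest voids first: the rejection sampler then always packs the
      # hard cases into an empty seed
      for (i in order(-max_ax_vox)) {
        rot[[i]] <- random_rotation()
        room <- ax_vox - max_ax_vox[i] - 1
        cv_assert(all(room > 0), "charvoid_geometry_error",
                  "hole of semi-axis %.0f um does not fit inside the seed",
                  max(holes$a_um[i], holes$b_um[i], holes$c_um[i]))
        for (attempt in seq_len(1000L)) {
          if (attempt > 1L) rot[[i]] <- random_rotation()
          p <- centre + runif_ball() * room
          if (!resolvable[i] || length(placed) == 0) break
          ok <- TRUE
          for (j in placed) {
            dvec <- p - centres[j, ]
            d <- sqrt(sum(dvec^2))
            u <- dvec / d
            if (d <= support(i, u) + support(j, u) + 1.5) {
              ok <- FALSE
              break
            }
          }
          if (ok) break
        }
        centres[i, ] <- p
        if (resolvable[i]) placed <- c(placed, i)
      }
    }
    break_normal <- if (spec$break_flag) {
      nv <- stats::rnorm(3)
      nv / sqrt(sum(nv^2))
    } else NULL
  })

  # --- render -------------------------------------------------------------
  vol <- render_seed_volume(dims, centre, ax_vox, spec$char_intensity,
                            holes, centres, rot, spec$voxel_size,
                            break_normal)

  if (n <- nrow(holes)) {
    holes$center_z <- centres[, 1]
    holes$center_y <- centres[, 2]
    holes$center_x <- centres[, 3]
  } else {
    holes$center_z <- numeric(0)
    holes$center_y <- numeric(0)
    holes$center_x <- numeric(0)
  }
  if (spec$break_flag) {
    holes <- dplyr::bind_rows(holes, tibble::tibble(
      class = "break", category = NA_character_,
      a_um = max(ax_mm) * 1000, b_um = max(ax_mm) * 1000,
      c_um = 1.2 * spec$voxel_size, volume_mm3 = NA_real_, v = NA_real_,
      center_z = centre[1], center_y = centre[2], center_x = centre[3]
    ))
  }

  rates <- pop$rates
  structure(list(
    volume = vol,
    ground_truth = list(
      holes = holes,
      envelope_volume_mm3 = pop$V_seed,
      expected_counts = c(Small = rates$lambda_small,
                          Medium = rates$lambda_medium,
                          Large = rates$lambda_large),
      spec = spec
    )
  ), class = "seed_phantom")
}

# Voxelize the seed body and carve the voids. dims/centre/ax in voxels.
render_seed_volume <- function(dims, centre, ax_vox, char_intensity,
                               holes, centres, rot, voxel_size,
                               break_normal = NULL) {
  dz2 <- ((seq_len(dims[1]) - 1 - centre[1]) / ax_vox[1])^2
  dy2 <- ((seq_len(dims[2]) - 1 - centre[2]) / ax_vox[2])^2
  dx2 <- ((seq_len(dims[3]) - 1 - centre[3]) / ax_vox[3])^2
  inside <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= 1
  vol <- array(0, dims)
  vol[inside] <- char_intensity

  carve <- function(vol, c_vox, axes_vox, R) {
    r <- max(axes_vox)
    zr <- max(1, floor(c_vox[1] - r)):min(dims[1], ceiling(c_vox[1] + r + 2))
    yr <- max(1, floor(c_vox[2] - r)):min(dims[2], ceiling(c_vox[2] + r + 2))
    xr <- max(1, floor(c_vox[3] - r)):min(dims[3], ceiling(c_vox[3] + r + 2))
    g <- as.matrix(expand.grid(z = zr - 1, y = yr - 1, x = xr - 1))
    q <- (g - matrix(c_vox, nrow(g), 3, byrow = TRUE)) %*% R
    hit <- (q[, 1] / axes_vox[1])^2 + (q[, 2] / axes_vox[2])^2 +
      (q[, 3] / axes_vox[3])^2 <= 1
    if (any(hit)) {
      idx <- g[hit, , drop = FALSE] + 1
      vol[cbind(idx[, 1], idx[, 2], idx[, 3])] <- 0
    }
    vol
  }

  for (i in seq_len(nrow(holes))) {
    axes_vox <- c(holes$a_um[i], holes$b_um[i], holes$c_um[i]) / voxel_size
    if (max(axes_vox) < 0.25) next  # far below a voxel: nothing to carve
    vol <- carve(vol, centres[i, ], axes_vox, rot[[i]])
  }

  if (!is.null(break_normal)) {
    g <- which(inside, arr.ind = TRUE) - 1
    d <- abs((g[, 1] - centre[1]) * break_normal[1] +
               (g[, 2] - centre[2]) * break_normal[2] +
               (g[, 3] - centre[3]) * break_normal[3])
    cut <- d <= 1.2
    if (any(cut)) {
      idx <- g[cut, , drop = FALSE] + 1
      vol[cbind(idx[, 1], idx[, 2], idx[, 3])] <- 0
    }
  }

  attr(vol, "voxel_size_um") <- voxel_size
  vol
}
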