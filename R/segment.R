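#' Otsu threshold of an intensity volume
#'
#' Classical between-class-variance maximization on a 256-bin histogram of
#' the full 3D volume.
#'
#' @param x Numeric array of intensities.
#' @param levels Number of histogram bins.
#' @return Threshold on the intensity scale of `x`; voxels strictly above
#'   it are foreground.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  rng <- range(x, finite = TRUE)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = levels + 1)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = levels)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(levels + 1)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[levels]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  breaks[which.max(sigma_b) + 1]
}

#' Label connected components of a 3D binary mask
#'
#' @param mask Logical 3D array.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return Integer array of the same shape; 0 is background, components
#'   are numbered from 1 in raster-scan order of their first voxel.
#' @export
label_components <- function(mask, connectivity = 6L) {
  cv_assert(is.array(mask) && length(dim(mask)) == 3,
            "charvoid_validation_error", "mask must be a 3D array")
  label3d_cpp(as.logical(mask), as.integer(dim(mask)), as.integer(connectivity))
}

# Binary dilation/erosion with a 3x3x3 box, via shifted copies.
shift3 <- function(a, dz, dy, dx) {
  d <- dim(a)
  out <- array(FALSE, d)
  zs <- max(1, 1 + dz):min(d[1], d[1] + dz)
  ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
  xs <- max(1, 1 + dx):min(d[3], d[3] + dx)
  out[zs, ys, xs] <- a[zs - dz, ys - dy, xs - dx]
  out
}

dilate_box <- function(a) {
  out <- a
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    out <- out | shift3(a, dz, dy, dx)
  }
  out
}

erode_box <- function(a) {
  out <- a
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    out <- out & shift3(a, dz, dy, dx)
  }
  out
}

binary_close <- function(a, radius = 1L) {
  if (radius < 1) return(a)
  for (i in seq_len(radius)) a <- dilate_box(a)
  for (i in seq_len(radius)) a <- erode_box(a)
  a
}

# Component ids of `mask_lab` present on the grid border.
border_labels <- function(lab) {
  d <- dim(lab)
  ids <- c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
           lab[, , 1], lab[, , d[3]])
  unique(ids[ids > 0])
}

#' Segment the seed envelope from a grayscale volume
#'
#' Threshold (Otsu by default), keep the largest 26-connected material
#' object, close it with a 3x3x3 box (sealing narrow channel mouths), and
#' fill every cavity not 6-connected to the grid border. The filled region
#' is the seed envelope: char material plus all enclosed voids, the
#' divisor used for normalized hole metrics.
#'
#' @param v 3D numeric array (z, y, x); voxel size um taken from its
#'   `voxel_size_um` attribute unless given.
#' @param threshold `"otsu"` or a numeric intensity threshold.
#' @param voxel_size Voxel size in um; scalar or length-3 (z, y, x) for
#'   anisotropic voxels.
#' @param close_radius Closing radius in voxels (0 disables).
#' @return An object of class `seed_mask`: list with logical arrays
#'   `envelope` and `material`, `voxel_size` (um, length 3),
#'   `envelope_volume_mm3`, `material_volume_mm3` and the `threshold`
#'   used.
#' @export
segment_seed <- function(v, threshold = "otsu", voxel_size = NULL,
                         close_radius = 1L) {
  cv_assert(is.array(v) && length(dim(v)) == 3, "charvoid_validation_error",
            "v must be a 3D array")
  vs <- voxel_size %||% attr(v, "voxel_size_um")
  cv_assert(!is.null(vs) && all(vs > 0), "charvoid_validation_error",
            "voxel size (um) is required, via attribute or argument")
  vs <- rep(as.numeric(vs), length.out = 3)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(v) else {
    cv_assert(is.numeric(threshold) && length(threshold) == 1,
              "charvoid_validation_error",
              "threshold must be \"otsu\" or a single number")
    threshold
  }
  material_all <- v > thr
  if (!any(material_all)) {
    cv_stop("charvoid_no_seed", "no foreground voxels above threshold %g", thr)
  }
  lab <- label_components(material_all, 26L)
  sizes <- tabulate(lab[lab > 0])
  material <- array(lab == which.max(sizes), dim(v))

  closed <- binary_close(material, close_radius)
  bglab <- label_components(!closed, 6L)
  exterior <- array(bglab > 0 & (bglab %in% border_labels(bglab)), dim(v))
  envelope <- !exterior

  voxel_mm3 <- prod(vs) * 1e-9
  structure(list(
    envelope = envelope, material = material, voxel_size = vs,
    envelope_volume_mm3 = sum(envelope) * voxel_mm3,
    material_volume_mm3 = sum(material) * voxel_mm3,
    threshold = thr
  ), class = "seed_mask")
}

#' Extract interior void components from a segmented seed
#'
#' Labels the 6-connected components of envelope-minus-material and
#' measures each: voxel count, physical volume, centroid, principal
#' semi-axes from the second-moment (covariance) tensor of its voxel
#' coordinates (with the single-voxel 1/12 variance term, scaled per axis
#' for anisotropic voxels), planarity `c/a`, and whether the component is
#' connected to the background outside the seed surface.
#'
#' @param mask A `seed_mask` from [segment_seed()].
#' @return A tibble, one row per void component, with columns `label`,
#'   `voxel_count`, `volume_mm3`, `centroid_z/y/x` (0-based voxel
#'   coordinates), `a_um`, `b_um`, `c_um` (`a >= b >= c`), `planarity`,
#'   `touches_exterior`; attributes `envelope_volume_mm3` and
#'   `voxel_size`. A solid seed yields zero rows.
#' @export
extract_void_components <- function(mask) {
  stopifnot(inherits(mask, "seed_mask"))
  void <- mask$envelope & !mask$material
  vlab <- label_components(void, 6L)
  n_comp <- max(vlab)
  vs <- mask$voxel_size
  voxel_mm3 <- prod(vs) * 1e-9

  # background of the raw material mask; components reaching the grid
  # border are the exterior air, so any void voxel in them is connected to
  # the outside of the seed surface
  bglab <- label_components(!mask$material, 6L)
  ext_ids <- border_labels(bglab)

  rows <- vector("list", n_comp)
  idx <- which(vlab > 0)
  if (length(idx) > 0) {
    labs <- vlab[idx]
    coords <- arrayInd(idx, dim(vlab))
    ext_vox <- bglab[idx] %in% ext_ids
    for (cid in seq_len(n_comp)) {
      sel <- labs == cid
      xyz <- coords[sel, , drop = FALSE]
      cnt <- nrow(xyz)
      phys <- sweep(xyz - 1, 2, vs, `*`)
      cov_m <- if (cnt > 1) stats::cov(phys) * (cnt - 1) / cnt else
        matrix(0, 3, 3)
      cov_m <- cov_m + diag(vs^2 / 12)
      ev <- sort(eigen(cov_m, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)
      semi <- sqrt(5 * pmax(ev, 0))
      rows[[cid]] <- tibble::tibble(
        label = cid, voxel_count = cnt, volume_mm3 = cnt * voxel_mm3,
        centroid_z = mean(xyz[, 1] - 1), centroid_y = mean(xyz[, 2] - 1),
        centroid_x = mean(xyz[, 3] - 1),
        a_um = semi[1], b_um = semi[2], c_um = semi[3],
        planarity = if (semi[1] > 0) semi[3] / semi[1] else 1,
        touches_exterior = any(ext_vox[sel])
      )
    }
  }
  out <- if (n_comp > 0) dplyr::bind_rows(rows) else tibble::tibble(
    label = integer(), voxel_count = integer(), volume_mm3 = numeric(),
    centroid_z = numeric(), centroid_y = numeric(), centroid_x = numeric(),
    a_um = numeric(), b_um = numeric(), c_um = numeric(),
    planarity = numeric(), touches_exterior = logical()
  )
  attr(out, "envelope_volume_mm3") <- mask$envelope_volume_mm3
  attr(out, "voxel_size") <- vs
  out
}

#' Exclusion-rule thresholds for void classification
#'
#' @param n_min Minimum voxel count; smaller components are `outlier`
#'   (too small to be differentiated from noise).
#' @param tau_crack Planarity (`c/a`) below which an interior void is a
#'   `crack`.
#' @param f_break Fraction of the envelope volume above which a void is a
#'   cotyledon-separation `break`.
#' @param tau_break Planarity below which an exterior-connected void is a
#'   `break`.
#' @return A named list of class `classifier_rules`.
#' @export
classifier_rules <- function(n_min = 10L, tau_crack = 0.15, f_break = 0.05,
                             tau_break = 0.3) {
  structure(list(n_min = n_min, tau_crack = tau_crack, f_break = f_break,
                 tau_break = tau_break), class = "classifier_rules")
}

#' Classify void components as hole, crack, break or outlier
#'
#' Applies the exclusion rules in order: components below `n_min` voxels
#' are outliers; components larger than `f_break` of the envelope, or
#' exterior-connected and plate-like, are breaks; plate-like interior
#' components (`planarity < tau_crack`) are cracks; everything else is a
#' hole. Only `klass == "hole"` components enter quantification (cracks
#' thick enough to evade `tau_crack` pass as holes and are reported as
#' contamination by [crack_contamination()]).
#'
#' @param components Tibble from [extract_void_components()].
#' @param rules A [classifier_rules()].
#' @param envelope_volume_mm3 Envelope volume; default from the tibble's
#'   attribute.
#' @return The input with a `klass` column added.
#' @export
classify_components <- function(components, rules = classifier_rules(),
                                envelope_volume_mm3 = NULL) {
  env_vol <- envelope_volume_mm3 %||% attr(components, "envelope_volume_mm3")
  cv_assert(!is.null(env_vol) && env_vol > 0, "charvoid_validation_error",
            "envelope_volume_mm3 is required")
  components$klass <- dplyr::case_when(
    components$voxel_count < rules$n_min ~ "outlier",
    components$volume_mm3 > rules$f_break * env_vol |
      (components$touches_exterior & components$planarity < rules$tau_break) ~
      "break",
    components$planarity < rules$tau_crack ~ "crack",
    TRUE ~ "hole"
  )
  components
}

#' Match measured components to ground-truth voids
#'
#' Assigns each component the nearest ground-truth void (by centroid
#' distance in voxels, within the void's own extent plus a 2-voxel slack)
#' and records its true class.
#'
#' @param components Classified component tibble.
#' @param ground_truth Ground-truth hole tibble from
#'   [generate_seed_phantom()] (`center_z/y/x`, semi-axes um, `class`).
#' @param voxel_size Voxel size um.
#' @return `components` with `true_class` and `gt_index` columns (`NA`
#'   when unmatched).
#' @export
match_components <- function(components, ground_truth, voxel_size) {
  vs <- rep(as.numeric(voxel_size), length.out = 3)
  components$true_class <- NA_character_
  components$gt_index <- NA_integer_
  if (nrow(components) == 0 || nrow(ground_truth) == 0) return(components)
  gt_xyz <- as.matrix(ground_truth[, c("center_z", "center_y", "center_x")])
  gt_reach <- pmax(ground_truth$a_um, ground_truth$b_um,
                   ground_truth$c_um, na.rm = TRUE) / mean(vs) + 2
  for (i in seq_len(nrow(components))) {
    p <- c(components$centroid_z[i], components$centroid_y[i],
           components$centroid_x[i])
    d <- sqrt(rowSums(sweep(gt_xyz, 2, p)^2))
    j <- which.min(d)
    if (d[j] <= gt_reach[j]) {
      components$true_class[i] <- ground_truth$class[j]
      components$gt_index[i] <- j
    }
  }
  components
}

#' Crack contamination of the retained hole set
#'
#' Fraction of the components classified as holes that are, per ground
#' truth, cracks — the quantity reported as "less than 1 percent" in
#' charred-seed hole statistics.
#'
#' @param components Classified components carrying a `true_class` column
#'   (see [match_components()]).
#' @return A single number in `[0, 1]`; `NA` (flagged undefined) when no
#'   component was classified as a hole.
#' @export
crack_contamination <- function(components) {
  cv_assert("klass" %in% names(components) &&
              "true_class" %in% names(components),
            "charvoid_validation_error",
            "components must carry klass and true_class columns")
  as_hole <- components$klass == "hole"
  if (!any(as_hole)) {
    return(structure(NA_real_, undefined = TRUE))
  }
  sum(as_hole & !is.na(components$true_class) &
        components$true_class == "crack") / sum(as_hole)
}
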