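#' Decade edges of the normalized hole-volume categories
#'
#' Normalized hole volume `v` (hole volume / seed envelope volume) is
#' binned into half-open decades with inclusive lower edges: Small
#' `[1e-7, 1e-6)`, Medium `[1e-6, 1e-5)`, Large `[1e-5, 1e-4)`. Values
#' below 1e-7 fall outside the measurable range (the "too small to be
#' differentiated" exclusion); values at or above 1e-4 are flagged rather
#' than silently kept.
#'
#' @format Named list of length-2 numeric vectors.
#' @export
hole_category_edges <- list(
  Small  = c(1e-7, 1e-6),
  Medium = c(1e-6, 1e-5),
  Large  = c(1e-5, 1e-4)
)

#' Categorize normalized hole volumes
#'
#' @param v Numeric vector of normalized hole volumes, all `> 0`.
#' @return Factor with levels `below_range`, `Small`, `Medium`, `Large`,
#'   `above_range`.
#' @examples
#' categorize(c(5e-7, 1e-6, 9e-8))  # Small, Medium, below_range
#' @export
categorize <- function(v) {
  cv_assert(is.numeric(v) && all(is.finite(v)) && all(v > 0),
            "charvoid_validation_error",
            "normalized volumes must be positive finite numbers")
  cut(v, breaks = c(0, 1e-7, 1e-6, 1e-5, 1e-4, Inf), right = FALSE,
      labels = c("below_range", "Small", "Medium", "Large", "above_range"))
}

#' Normalize hole volumes by the seed envelope volume
#'
#' Computes `v_i = V_i / V_seed` for each retained hole and sorts the
#' table by descending `v` (ties broken by component label, so the order
#' is stable and scale-invariant: rescaling the voxel size rescales every
#' `V_i` and `V_seed` by the same factor and leaves `v` unchanged).
#'
#' @param holes Tibble with columns `label` and `volume_mm3` (e.g. the
#'   `klass == "hole"` rows of [classify_components()] output), or a bare
#'   numeric vector of volumes.
#' @param V_seed Seed envelope volume in the same units (`> 0`).
#' @param seed_id Optional identifier stored as an attribute.
#' @return A `hole_table` tibble with columns `label`, `volume_mm3`, `v`,
#'   `category`; attributes `V_seed` and `seed_id`.
#' @export
normalize_holes <- function(holes, V_seed, seed_id = NA_character_) {
  cv_assert(is.numeric(V_seed) && length(V_seed) == 1 && V_seed > 0,
            "charvoid_validation_error", "V_seed must be a single value > 0")
  if (is.numeric(holes) && is.null(dim(holes))) {
    holes <- tibble::tibble(label = seq_along(holes), volume_mm3 = holes)
  }
  cv_assert(all(c("label", "volume_mm3") %in% names(holes)),
            "charvoid_validation_error",
            "holes must have label and volume_mm3 columns")
  cv_assert(all(holes$volume_mm3 > 0), "charvoid_validation_error",
            "hole volumes must be > 0")
  out <- tibble::tibble(
    label = holes$label,
    volume_mm3 = holes$volume_mm3,
    v = holes$volume_mm3 / V_seed
  )
  out$category <- categorize(out$v)
  out <- out[order(-out$v, out$label), ]
  attr(out, "V_seed") <- V_seed
  attr(out, "seed_id") <- seed_id
  class(out) <- c("hole_table", class(out))
  out
}

#' Per-seed summary metrics of the retained holes
#'
#' @param table A `hole_table` from [normalize_holes()].
#' @return A one-row tibble: `seed_id`, category counts (`n_small`,
#'   `n_medium`, `n_large`), `n_retained` (their sum), `excluded_below_small`
#'   and `flagged_above_range` counts, `normalized_count` (`n_retained /
#'   V_seed`, mm^-3), and `total_normalized_volume` (the unitless porosity
#'   `sum(v)` over retained holes).
#' @export
seed_metrics <- function(table) {
  stopifnot(inherits(table, "hole_table"))
  V_seed <- attr(table, "V_seed")
  cnt <- table(table$category)
  in_range <- table$category %in% c("Small", "Medium", "Large")
  tibble::tibble(
    seed_id = attr(table, "seed_id"),
    n_small = as.integer(cnt[["Small"]]),
    n_medium = as.integer(cnt[["Medium"]]),
    n_large = as.integer(cnt[["Large"]]),
    n_retained = as.integer(sum(in_range)),
    excluded_below_small = as.integer(cnt[["below_range"]]),
    flagged_above_range = as.integer(cnt[["above_range"]]),
    normalized_count = sum(in_range) / V_seed,
    total_normalized_volume = sum(table$v[in_range])
  )
}

#' Rank-size curve of a seed's holes
#'
#' Holes sorted from large to small; the pair (rank, normalized volume)
#' traces the seed's hole-size spectrum. A long tail of small holes
#' signals high oil content; a high head of large holes signals high
#' protein.
#'
#' @param table A `hole_table` from [normalize_holes()] (already sorted
#'   descending, ties broken by label).
#' @return Tibble with columns `rank` (1..N), `v`, `label`; empty for an
#'   empty table.
#' @export
rank_curve <- function(table) {
  stopifnot(inherits(table, "hole_table"))
  tibble::tibble(rank = seq_len(nrow(table)), v = table$v,
                 label = table$label)
}

#' Product of seed length, width and thickness
#'
#' The L x W x T product (mm^3) used to compare overall seed size, rounded
#' to one decimal as conventionally printed: a 5.1 x 2.5 x 2.4 mm seed has
#' product 30.6, a 4.4 x 2.7 x 3.0 mm seed 35.6.
#'
#' @param L,W,T Seed dimensions in mm, all `> 0`.
#' @return `L * W * T` rounded to one decimal place.
#' @export
dimension_product <- function(L, W, T) {
  cv_assert(is.numeric(L) && is.numeric(W) && is.numeric(T) &&
              all(c(L, W, T) > 0),
            "charvoid_validation_error", "all dimensions must be > 0")
  round(L * W * T, 1)
}
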