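#' The three reference cultivars with printed compositions
#'
#' Meng (protein 48.7%, oil 19.2%), Fu (42.5%, 15%) and Tiefeng (33.9%,
#' 23.6%) — the control groups whose Small/Medium/Large contrasts the
#' generator is required to reproduce.
#'
#' @return Tibble with columns `cultivar`, `label`, `protein_pct`,
#'   `oil_pct`.
#' @export
reference_cultivars <- function() {
  tibble::tibble(
    cultivar = c("Meng", "Fu", "Tiefeng"),
    label = c("P48.7O19.2", "P42.5O15", "P33.9O23.6"),
    protein_pct = c(48.7, 42.5, 33.9),
    oil_pct = c(19.2, 15, 23.6)
  )
}

# Per-seed category metrics from a phantom's ground-truth hole table,
# routed through the normalization/categorization pipeline.
ground_truth_metrics <- function(spec, seed_id = NA_character_) {
  gt <- simulate_hole_table(spec)
  holes <- gt$holes[gt$holes$class == "hole", , drop = FALSE]
  if (nrow(holes) == 0) {
    tab <- normalize_holes(tibble::tibble(label = 1L, volume_mm3 = 1),
                           1, seed_id = seed_id)[0, ]
    attr(tab, "V_seed") <- gt$envelope_volume_mm3
    attr(tab, "seed_id") <- seed_id
    class(tab) <- c("hole_table", class(tibble::tibble()))
  } else {
    tab <- normalize_holes(
      tibble::tibble(label = seq_len(nrow(holes)),
                     volume_mm3 = holes$volume_mm3),
      gt$envelope_volume_mm3, seed_id = seed_id)
  }
  m <- seed_metrics(tab)
  m$V_seed_mm3 <- gt$envelope_volume_mm3
  m
}

#' Replicated cultivar-contrast experiment
#'
#' Generates `n_seeds` phantoms per reference cultivar (charred dry at
#' 275 degC), quantifies each seed's ground-truth hole table, and tests
#' the per-category normalized counts across cultivars with one-way
#' ANOVA. For each replicate suite the two reported contrasts are
#' checked: the high-oil cultivar (P33.9O23.6) has the greatest
#' Small-category mean and the high-protein cultivar (P48.7O19.2) the
#' greatest Large-category mean, each with ANOVA p below `alpha`.
#'
#' @param n_suites Number of independently seeded replicate suites.
#' @param n_seeds Seeds per cultivar per suite.
#' @param base_seed Integer seed; suite `s`, seed `i` of cultivar `c`
#'   uses `base_seed + 10000 * s + 100 * c + i`.
#' @param alpha ANOVA significance level.
#' @return Tibble with one row per suite: `suite`, `p_small`, `p_large`,
#'   `small_top` / `large_top` (label of the group with the greatest
#'   mean), `small_ok`, `large_ok`, `pass`.
#' @export
run_cultivar_suite <- function(n_suites = 20, n_seeds = 7, base_seed = 1L,
                               alpha = 0.05) {
  cult <- reference_cultivars()
  out <- vector("list", n_suites)
  for (s in seq_len(n_suites)) {
    metrics <- list()
    for (ci in seq_len(nrow(cult))) {
      for (i in seq_len(n_seeds)) {
        spec <- phantom_spec(cult$protein_pct[ci], cult$oil_pct[ci],
                             rng_seed = base_seed + 10000L * s +
                               100L * ci + i)
        m <- ground_truth_metrics(spec, seed_id = sprintf("%s_%d",
                                                          cult$label[ci], i))
        m$group <- cult$label[ci]
        metrics[[length(metrics) + 1]] <- m
      }
    }
    metrics <- dplyr::bind_rows(metrics)
    test_cat <- function(col) {
      vals <- metrics[[col]] / metrics$V_seed_mm3
      groups <- split(vals, metrics$group)
      an <- oneway_anova(groups)
      list(p = an$p, top = names(which.max(an$group_means)))
    }
    sm <- test_cat("n_small")
    lg <- test_cat("n_large")
    out[[s]] <- tibble::tibble(
      suite = s, p_small = sm$p, p_large = lg$p,
      small_top = sm$top, large_top = lg$top,
      small_ok = sm$top == "P33.9O23.6" && sm$p < alpha,
      large_ok = lg$top == "P48.7O19.2" && lg$p < alpha
    )
  }
  out <- dplyr::bind_rows(out)
  out$pass <- out$small_ok & out$large_ok
  out
}

#' Replicated charring-temperature experiment
#'
#' For each replicate suite, `n_seeds` high-oil (P33.9O23.6) phantoms
#' charred at 275 degC are compared with `n_seeds` charred at 300 degC by
#' two-tailed t tests on the per-category normalized counts. The
#' generator halves the Small-category rate at 300 degC, so the Small
#' contrast should be significant and Medium/Large should not.
#'
#' @inheritParams run_cultivar_suite
#' @return Tibble with one row per suite: `suite`, `p_small`, `p_medium`,
#'   `p_large`, and the Small-category means at each temperature.
#' @export
run_temperature_suite <- function(n_suites = 100, n_seeds = 6,
                                  base_seed = 1L) {
  out <- vector("list", n_suites)
  for (s in seq_len(n_suites)) {
    metrics <- list()
    for (temp_i in 1:2) {
      temp <- c(275, 300)[temp_i]
      for (i in seq_len(n_seeds)) {
        spec <- phantom_spec(33.9, 23.6, char_temp = temp,
                             rng_seed = base_seed + 10000L * s +
                               1000L * temp_i + i)
        m <- ground_truth_metrics(spec)
        m$group <- as.character(temp)
        metrics[[length(metrics) + 1]] <- m
      }
    }
    metrics <- dplyr::bind_rows(metrics)
    pvals <- vapply(c("n_small", "n_medium", "n_large"), function(col) {
      vals <- metrics[[col]] / metrics$V_seed_mm3
      t_test_two_tailed(vals[metrics$group == "275"],
                        vals[metrics$group == "300"])$p
    }, 0)
    sm <- metrics$n_small / metrics$V_seed_mm3
    out[[s]] <- tibble::tibble(
      suite = s, p_small = pvals[1], p_medium = pvals[2],
      p_large = pvals[3],
      mean_small_275 = mean(sm[metrics$group == "275"]),
      mean_small_300 = mean(sm[metrics$group == "300"])
    )
  }
  dplyr::bind_rows(out)
}

#' Water-saturation check
#'
#' Generates water-saturated phantoms (soaked before charring: envelope
#' enlarged 1.4x linearly, Small and Medium hole rates forced to zero) and
#' counts ground-truth holes with normalized volume below 1e-5.
#'
#' @param n_seeds Number of saturated phantoms.
#' @param base_seed Integer seed.
#' @return List with `holes_below_1e5` (total count, expected 0),
#'   `total_holes`, and the per-seed hole tables.
#' @export
water_saturation_check <- function(n_seeds = 5, base_seed = 1L) {
  tables <- lapply(seq_len(n_seeds), function(i) {
    spec <- phantom_spec(40, 20, water_saturated = TRUE,
                         rng_seed = base_seed + i)
    simulate_hole_table(spec)
  })
  holes <- dplyr::bind_rows(lapply(tables, function(t) {
    t$holes[t$holes$class == "hole", , drop = FALSE]
  }))
  list(holes_below_1e5 = sum(holes$v < 1e-5),
       total_holes = nrow(holes),
       tables = tables)
}

#' Phantom spec for segmentation validation at voxel-resolvable hole sizes
#'
#' A reduced seed (1.1 x 0.9 x 0.8 mm at 10 um voxels, ~110 voxels along
#' the long axis) carrying a known number of large voids (mean radius
#' 35-80 um, i.e. 3.5-8 voxel semi-axes) and thin cracks, so that every
#' ground-truth void is comfortably above the `n_min` exclusion and
#' voxelization error stays below 10%.
#'
#' @param n_holes Expected hole count (Poisson mean).
#' @param crack_count Number of cracks.
#' @param rng_seed Integer seed.
#' @export
validation_phantom_spec <- function(n_holes = 12, crack_count = 2,
                                    rng_seed = 1L) {
  phantom_spec(
    protein_pct = 40, oil_pct = 20,
    semi_axes = c(0.55, 0.45, 0.40), voxel_size = 10,
    crack_count = crack_count, rng_seed = rng_seed,
    rate_override = list(lambda_small = 0, lambda_medium = 0,
                         lambda_large = n_holes),
    hole_radius_um = list(Large = c(35, 80))
  )
}

#' Segmentation validation against phantom ground truth
#'
#' Runs the full segment -> extract -> classify chain on rendered
#' validation phantoms and scores it against the generator's ground
#' truth: hole recovery (fraction of ground-truth holes matched by a
#' component classified as a hole), per-hole volume error versus the
#' analytic ellipsoid volume, and crack contamination of the retained
#' hole set.
#'
#' @param n_seeds Number of validation phantoms.
#' @param base_seed Integer seed.
#' @param rules [classifier_rules()] to apply.
#' @return List with `recovery` (fraction), `median_volume_error`,
#'   `max_volume_error`, `contamination`, and the pooled per-component
#'   table.
#' @export
run_segmentation_validation <- function(n_seeds = 12, base_seed = 1L,
                                        rules = classifier_rules()) {
  all_comp <- list()
  n_gt <- 0L
  n_recovered <- 0L
  vol_err <- numeric()
  for (i in seq_len(n_seeds)) {
    spec <- validation_phantom_spec(rng_seed = base_seed + i)
    ph <- generate_seed_phantom(spec)
    mask <- segment_seed(ph$volume)
    comp <- classify_components(extract_void_components(mask), rules)
    comp <- match_components(comp, ph$ground_truth$holes, spec$voxel_size)
    gt_holes <- ph$ground_truth$holes[ph$ground_truth$holes$class == "hole", ]
    n_gt <- n_gt + nrow(gt_holes)
    matched <- comp[comp$klass == "hole" & !is.na(comp$gt_index) &
                      comp$true_class == "hole", , drop = FALSE]
    n_recovered <- n_recovered + length(unique(matched$gt_index))
    if (nrow(matched) > 0) {
      truth <- ph$ground_truth$holes$volume_mm3[matched$gt_index]
      vol_err <- c(vol_err, abs(matched$volume_mm3 - truth) / truth)
    }
    comp$seed <- i
    all_comp[[i]] <- comp
  }
  comp <- dplyr::bind_rows(all_comp)
  list(
    recovery = n_recovered / n_gt,
    median_volume_error = stats::median(vol_err),
    max_volume_error = max(vol_err),
    contamination = crack_contamination(comp),
    components = comp
  )
}

#' Type-I error of the one-way ANOVA under a normal null
#'
#' @param n_reps Replicates.
#' @param n_groups,n Group count and per-group size.
#' @param base_seed Integer seed.
#' @param alpha Level.
#' @return Fraction of replicates with ANOVA `p < alpha`.
#' @export
anova_type1_rate <- function(n_reps = 2000, n_groups = 3, n = 7,
                             base_seed = 1L, alpha = 0.05) {
  withr::with_seed(base_seed, {
    mean(vapply(seq_len(n_reps), function(r) {
      groups <- lapply(seq_len(n_groups), function(g) stats::rnorm(n))
      oneway_anova(groups)$p < alpha
    }, logical(1)))
  })
}

#' Family-wise error of Dunnett's T3 under an unequal-variance null
#'
#' Simulates groups with equal means but different variances and counts
#' replicates in which any adjusted pairwise p-value falls below `alpha`.
#'
#' @param n_reps Replicates.
#' @param n Per-group size.
#' @param sds Group standard deviations (length = group count).
#' @param base_seed Integer seed.
#' @param alpha Level.
#' @return Fraction of replicates with at least one rejection.
#' @export
t3_familywise_error <- function(n_reps = 2000, n = 7, sds = c(1, 2, 5),
                                base_seed = 1L, alpha = 0.05) {
  withr::with_seed(base_seed, {
    mean(vapply(seq_len(n_reps), function(r) {
      groups <- lapply(sds, function(s) stats::rnorm(n, sd = s))
      any(dunnett_t3(groups)$p < alpha)
    }, logical(1)))
  })
}

#' Selection rate of the Levene gate under equal variances
#'
#' @param n_reps Replicates.
#' @param n_groups,n Group count and per-group size.
#' @param base_seed Integer seed.
#' @return Fraction of replicates in which [variance_gate()] selects the
#'   equal-variance (LSD) family.
#' @export
levene_gate_rate <- function(n_reps = 1000, n_groups = 3, n = 7,
                             base_seed = 1L) {
  withr::with_seed(base_seed, {
    mean(vapply(seq_len(n_reps), function(r) {
      groups <- lapply(seq_len(n_groups), function(g) stats::rnorm(n))
      variance_gate(groups)$posthoc_method == "LSD"
    }, logical(1)))
  })
}
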