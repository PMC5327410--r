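#' Run the phantom -> segment -> quantify -> stats pipeline
#'
#' Executes the enabled stages of a [default_run_config()] in order and
#' writes the tabular results to `config$out_dir`:
#'
#' * `metrics.csv` — one row per seed: category counts, normalized count,
#'   total normalized volume;
#' * `rank_curves.csv` — per-seed rank-size curves (`seed_id`, `rank`, `v`);
#' * `comparison_<category>.json` — group-comparison reports (when the
#'   stats stage runs and at least two groups are present);
#' * `run_log.json` — parameter echo, versions and RNG seed.
#'
#' Inputs are either per-seed phantom parameters in `config$seeds` (each a
#' named list passed to [phantom_spec()], plus optional `id` and `group`)
#' or paths to existing volumes in `config$volumes` (each `list(id, group,
#' path)`). With the segment stage enabled, holes are measured from the
#' voxel data and normalized by the measured envelope volume; with it
#' disabled (phantom inputs only), the generator's ground-truth hole
#' tables are quantified directly, normalized by the analytic envelope
#' volume.
#'
#' @param config A `run_config` list.
#' @return Invisibly, a list with `metrics`, `curves`, `comparisons`.
#' @export
run_pipeline <- function(config) {
  cv_assert(!is.null(config$out_dir), "charvoid_validation_error",
            "config$out_dir is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  rules <- classifier_rules(n_min = config$n_min,
                            tau_crack = config$tau_crack,
                            f_break = config$f_break,
                            tau_break = config$tau_break)

  inputs <- list()
  if (isTRUE(config$stages$phantom)) {
    cv_assert(length(config$seeds) > 0, "charvoid_validation_error",
              "phantom stage enabled but config$seeds is empty")
    for (i in seq_along(config$seeds)) {
      s <- config$seeds[[i]]
      id <- s$id %||% sprintf("seed%02d", i)
      group <- s$group %||% "all"
      s$id <- NULL
      s$group <- NULL
      if (is.null(s$voxel_size)) s$voxel_size <- config$voxel_size_um
      if (is.null(s$rng_seed)) s$rng_seed <- config$rng_seed + i
      ph <- generate_seed_phantom(do.call(phantom_spec, s))
      inputs[[i]] <- list(id = id, group = group, volume = ph$volume,
                          ground_truth = ph$ground_truth)
    }
  } else {
    cv_assert(length(config$volumes) > 0, "charvoid_validation_error",
              "phantom stage disabled and no input volumes configured")
    for (i in seq_along(config$volumes)) {
      vv <- config$volumes[[i]]
      cv_assert(!is.null(vv$path) && file.exists(vv$path),
                "charvoid_io_error", "missing input volume: %s",
                vv$path %||% "<unset>")
      inputs[[i]] <- list(id = vv$id %||% sprintf("seed%02d", i),
                          group = vv$group %||% "all",
                          volume = read_volume(vv$path),
                          ground_truth = NULL)
    }
  }

  metrics <- list()
  curves <- list()
  for (i in seq_along(inputs)) {
    inp <- inputs[[i]]
    if (isTRUE(config$stages$segment)) {
      mask <- segment_seed(inp$volume, threshold = config$threshold,
                           close_radius = config$close_radius)
      comp <- classify_components(extract_void_components(mask), rules)
      holes <- comp[comp$klass == "hole",
                    c("label", "volume_mm3"), drop = FALSE]
      V_seed <- mask$envelope_volume_mm3
    } else {
      cv_assert(!is.null(inp$ground_truth), "charvoid_validation_error",
                "segment stage disabled but no ground truth available")
      gh <- inp$ground_truth$holes
      gh <- gh[gh$class == "hole", , drop = FALSE]
      holes <- tibble::tibble(label = seq_len(nrow(gh)),
                              volume_mm3 = gh$volume_mm3)
      V_seed <- inp$ground_truth$envelope_volume_mm3
    }
    if (!isTRUE(config$stages$quantify)) next
    if (nrow(holes) == 0) {
      tab <- structure(
        tibble::tibble(label = integer(), volume_mm3 = numeric(),
                       v = numeric(),
                       category = categorize(1e-6)[0]),
        V_seed = V_seed, seed_id = inp$id,
        class = c("hole_table", class(tibble::tibble())))
    } else {
      tab <- normalize_holes(holes, V_seed, seed_id = inp$id)
    }
    m <- seed_metrics(tab)
    m$group <- inp$group
    m$V_seed_mm3 <- V_seed
    metrics[[i]] <- m
    rc <- rank_curve(tab)
    if (nrow(rc) > 0) {
      rc$seed_id <- inp$id
      curves[[i]] <- rc[, c("seed_id", "rank", "v")]
    }
  }
  metrics <- dplyr::bind_rows(metrics)
  curves <- dplyr::bind_rows(curves)
  if (nrow(metrics) > 0) {
    utils::write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
                     row.names = FALSE)
  }
  if (nrow(curves) > 0) {
    utils::write.csv(curves, file.path(config$out_dir, "rank_curves.csv"),
                     row.names = FALSE)
  }

  comparisons <- list()
  if (isTRUE(config$stages$stats) && nrow(metrics) > 0 &&
      length(unique(metrics$group)) >= 2 &&
      all(table(metrics$group) >= 2)) {
    for (cat_col in c("n_small", "n_medium", "n_large")) {
      # normalized per-category count: count / V_seed, mm^-3
      vals <- metrics[[cat_col]] / metrics$V_seed_mm3
      groups <- split(vals, metrics$group)
      cmp <- tryCatch(compare_groups(groups, alpha = config$alpha),
                      charvoid_degenerate = function(e) NULL)
      if (is.null(cmp)) next
      rep <- list(
        category = sub("n_", "", cat_col),
        F = cmp$anova$F, df = as.list(cmp$anova$df), p_anova = cmp$anova$p,
        homogeneity_p = cmp$homogeneity_p,
        posthoc_method = cmp$posthoc_method,
        pairwise = cmp$posthoc
      )
      comparisons[[cat_col]] <- rep
      jsonlite::write_json(
        rep, file.path(config$out_dir,
                       sprintf("comparison_%s.json", sub("n_", "", cat_col))),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
  }

  log <- list(
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    package_version = as.character(utils::packageVersion("charvoid")),
    r_version = R.version.string,
    rng_seed = config$rng_seed,
    config = unclass(config[setdiff(names(config), "volumes")])
  )
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(metrics = metrics, curves = curves,
                 comparisons = comparisons))
}
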