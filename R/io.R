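#' Write a volume as a multi-page TIFF with a JSON metadata sidecar
#'
#' Slices (z pages of y-by-x matrices) are stored in a single TIFF. TIFF
#' samples live in `[0, 1]`, so the voxel values are affinely rescaled and
#' the scale recorded, together with the shape and voxel size, in
#' `<path>.json` (TIFF voxel-size tags are dialect-ridden; an explicit
#' sidecar is unambiguous). 32-bit float storage round-trips exactly at
#' single precision; 16-bit storage quantizes to 1/65535 of the value
#' range.
#'
#' @param v 3D numeric array (z, y, x); voxel size um read from its
#'   `voxel_size_um` attribute unless given.
#' @param path Output TIFF path; the sidecar is written next to it.
#' @param bits 32 (float) or 16 (unsigned integer) samples.
#' @param voxel_size_um Voxel size override.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, bits = 32L, voxel_size_um = NULL) {
  cv_assert(is.array(v) && length(dim(v)) == 3, "charvoid_validation_error",
            "v must be a 3D array")
  cv_assert(bits %in% c(16L, 32L), "charvoid_validation_error",
            "bits must be 16 or 32")
  vs <- voxel_size_um %||% attr(v, "voxel_size_um")
  vmin <- min(v)
  vmax <- max(v)
  scale <- if (vmax > vmin) vmax - vmin else 1
  pages <- lapply(seq_len(dim(v)[1]), function(z) (v[z, , ] - vmin) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  meta <- list(shape = dim(v), axis_order = "zyx",
               voxel_size_um = vs, vmin = vmin, vmax = vmax,
               bits_per_sample = as.integer(bits))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path TIFF path; `<path>.json` must exist beside it.
#' @return 3D numeric array (z, y, x) with a `voxel_size_um` attribute.
#' @export
read_volume <- function(path) {
  cv_assert(file.exists(path), "charvoid_io_error", "no such volume: %s", path)
  side <- paste0(path, ".json")
  cv_assert(file.exists(side), "charvoid_io_error",
            "missing metadata sidecar: %s", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) {
                      cv_stop("charvoid_format_error",
                              "cannot read TIFF %s: %s", path,
                              conditionMessage(e))
                    })
  shape <- as.integer(meta$shape)
  cv_assert(length(pages) == shape[1], "charvoid_format_error",
            "TIFF has %d pages but sidecar declares %d slices",
            length(pages), shape[1])
  cv_assert(all(dim(pages[[1]]) == shape[2:3]), "charvoid_format_error",
            "TIFF page shape does not match sidecar")
  scale <- if (meta$vmax > meta$vmin) meta$vmax - meta$vmin else 1
  v <- array(0, shape)
  for (z in seq_len(shape[1])) v[z, , ] <- pages[[z]] * scale + meta$vmin
  attr(v, "voxel_size_um") <- meta$voxel_size_um
  v
}

#' Write / read a ground-truth hole table as CSV
#'
#' One row per void: center (0-based voxel coordinates, z/y/x), semi-axes
#' in um, class, analytic volume and normalized volume.
#'
#' @param ground_truth The `ground_truth` element of a
#'   [generate_seed_phantom()] result.
#' @param path CSV path.
#' @return `path` (write) or a list mirroring the ground-truth structure
#'   (read).
#' @export
write_ground_truth <- function(ground_truth, path) {
  utils::write.csv(ground_truth$holes, path, row.names = FALSE)
  meta <- list(envelope_volume_mm3 = ground_truth$envelope_volume_mm3,
               expected_counts = as.list(ground_truth$expected_counts))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  cv_assert(file.exists(path), "charvoid_io_error",
            "no such ground truth: %s", path)
  holes <- tibble::as_tibble(utils::read.csv(path,
                                             stringsAsFactors = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  list(holes = holes,
       envelope_volume_mm3 = meta$envelope_volume_mm3,
       expected_counts = unlist(meta$expected_counts))
}

#' Default pipeline configuration
#'
#' Every tunable of the pipeline with its documented default. The single
#' `rng_seed` determines every stochastic stage.
#'
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    stages = list(phantom = TRUE, segment = TRUE, quantify = TRUE,
                  stats = TRUE),
    threshold = "otsu",
    n_min = 10L,
    tau_crack = 0.15,
    f_break = 0.05,
    tau_break = 0.3,
    close_radius = 1L,
    category_edges = c(1e-7, 1e-6, 1e-5, 1e-4),
    alpha = 0.05,
    voxel_size_um = 55,
    rng_seed = 1L,
    seeds = list(),       # per-seed phantom parameters (see run_pipeline)
    volumes = list(),     # or paths to existing volumes
    out_dir = NULL
  ), class = "run_config")
}

#' Write / read a pipeline configuration (YAML)
#'
#' Configurations round-trip losslessly.
#'
#' @param config A `run_config` list.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cv_assert(file.exists(path), "charvoid_io_error", "no such config: %s", path)
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  cfg$n_min <- as.integer(cfg$n_min)
  cfg$close_radius <- as.integer(cfg$close_radius)
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  for (nm in c("tau_crack", "f_break", "tau_break", "alpha",
               "voxel_size_um", "category_edges")) {
    cfg[[nm]] <- as.numeric(cfg[[nm]])
  }
  cfg
}
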