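#' Analysis configuration with published defaults
#'
#' All pipeline parameters by name, with the published default values:
#' elastin background thresholds of 15% (centerline fit) and 6% (media
#' density) of the maximum possible intensity; media KDE bandwidth 1.2 and
#' 20% edge level; 99.6% intensity stretch; vesselness scale 1.2 um with
#' sensitivities alpha = beta = c = 0.15 and segmentation threshold 0.1;
#' minimum structure volume 54 um^3; cell-density KDE bandwidth 1.0; and the
#' nucleus-splitting constants of [split_params()]. Additional numerical
#' controls (`fit_subsample`, `rho_cutoff`, `silhouette_sample`,
#' `max_structure_voxels`, `grid_step`, `seed`) are implementation details
#' documented in the vignette. Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `vessel_config`.
#' @export
vessel_config <- function(...) {
  defaults <- list(
    # vessel orientation
    elastin_threshold_fit = 0.15,
    # medial thickness determination
    elastin_threshold_media = 0.06,
    media_kde_bandwidth = 1.2,
    media_edge_level = 0.20,
    # intensity normalization + vesselness filtering
    intensity_keep_fraction = 0.996,
    vesselness_sigma = 1.2,
    vesselness_alpha = 0.15,
    vesselness_beta = 0.15,
    vesselness_c = 0.15,
    nucleus_threshold = 0.1,
    # nucleus extraction
    min_nucleus_volume = 54,
    # cell density distribution estimation
    density_bandwidth = 1.0,
    # nucleus splitting, steps 1-3
    sigma_r = 0.8,
    sigma_td = 0.8,
    d_min = 40,
    single_min_volume = 1.8,
    lambda1_max = 0.01,
    lambda2_min = 0.02,
    kmeans_restarts = 20L,
    k_max = 10L,
    sigma_vc = 2.0,
    sigma_vs = 5.0,
    small_core_voxels = 12L,
    # numerical controls
    fit_subsample = 2e5,
    rho_cutoff = 1e-6,
    silhouette_sample = 2000L,
    max_structure_voxels = 150000L,
    grid_step = 0.1,
    seed = 1L
  )
  over <- list(...)
  if (length(over) > 0L) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("all configuration overrides must be named")
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown) > 0L)
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    defaults[names(over)] <- over
  }
  structure(defaults, class = "vessel_config")
}

#' @export
print.vessel_config <- function(x, ...) {
  cat("vessel_config:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read a configuration from a YAML file
#'
#' @param path YAML file whose keys are [vessel_config()] keys.
#' @return A `vessel_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(vessel_config, vals)
}

.split_params_from_config <- function(config) {
  split_params(sigma_r = config$sigma_r, sigma_td = config$sigma_td,
               d_min = config$d_min,
               single_min_volume = config$single_min_volume,
               lambda1_max = config$lambda1_max,
               lambda2_min = config$lambda2_min, k_max = config$k_max,
               n_restarts = config$kmeans_restarts,
               sigma_vc = config$sigma_vc, sigma_vs = config$sigma_vs,
               small_core_voxels = config$small_core_voxels,
               rho_cutoff = config$rho_cutoff,
               silhouette_sample = config$silhouette_sample,
               max_voxels = config$max_structure_voxels)
}

#' Run the full nucleus-quantification pipeline on one scan
#'
#' Executes, in order: the (optional) deconvolution hook, per-channel
#' intensity stretching, centerline fitting on the elastin channel, media
#' border detection from the transmural elastin density, vesselness
#' filtering and segmentation of the nuclei channel, connected-structure
#' extraction, nucleus splitting of every structure, and quantification
#' (counts, transmural distributions with and without splitting, medial
#' cell density). Per-structure decisions and any stage errors are recorded
#' in the returned log; rerunning with the same inputs, configuration and
#' seed reproduces the result exactly.
#'
#' @param red Elastin-channel [image_stack()].
#' @param green Nuclei-channel [image_stack()].
#' @param config A [vessel_config()].
#' @param deconvolve Optional function `(stack) -> stack` applied to both
#'   channels before any analysis, marking where external deconvolution
#'   would run; the default is a pass-through.
#' @return A list of class `vessel_analysis`: `geometry`, `borders`,
#'   `structures`, `splits`, `counts`, `nuclei` (per-nucleus table),
#'   `distribution_with`/`distribution_without`, `density`, `log`, and the
#'   `config` used.
#' @export
run_pipeline <- function(red, green, config = vessel_config(),
                         deconvolve = NULL) {
  stopifnot(inherits(red, "image_stack"), inherits(green, "image_stack"),
            inherits(config, "vessel_config"))
  log <- list(config = unclass(config), stages = list())
  t0 <- Sys.time()
  if (!is.null(deconvolve)) {
    red <- deconvolve(red); green <- deconvolve(green)
    log$stages$deconvolve <- "external hook applied"
  } else log$stages$deconvolve <- "pass-through (stacks taken as provided)"

  red <- stretch_intensity(red, config$intensity_keep_fraction)
  green <- stretch_intensity(green, config$intensity_keep_fraction)

  geom <- fit_centerline(red, config$elastin_threshold_fit,
                         subsample = config$fit_subsample)
  log$stages$centerline <- list(direction = geom$direction,
                                point = geom$point,
                                residual = geom$fit_residual)

  dens <- transmural_density(red, geom, config$elastin_threshold_media,
                             config$media_kde_bandwidth, config$grid_step)
  borders <- detect_media_borders(dens, config$media_edge_level)
  log$stages$media <- list(r_inner = borders$r_inner,
                           r_outer = borders$r_outer)

  vf <- vesselness3d(green, config$vesselness_sigma, config$vesselness_alpha,
                     config$vesselness_beta, config$vesselness_c)
  mask <- segment_nuclei(vf, config$nucleus_threshold)
  structures <- extract_structures(mask, vf,
                                   min_volume = config$min_nucleus_volume)
  log$stages$extraction <- list(n_structures = length(structures),
                                mask_voxels = sum(mask))

  params <- .split_params_from_config(config)
  splits <- vector("list", length(structures))
  split_log <- vector("list", length(structures))
  for (s in seq_along(structures)) {
    seed_s <- as.integer((config$seed + 7919 * s) %% .Machine$integer.max)
    res <- tryCatch(
      split_structure(structures[[s]], geom, params, seed = seed_s),
      error = function(e) e)
    if (inherits(res, "error")) {
      # a failed stage leaves the structure whole but is reported
      splits[[s]] <- .single_result(structures[[s]])
      split_log[[s]] <- list(id = s, error = conditionMessage(res))
    } else {
      splits[[s]] <- res
      split_log[[s]] <- list(id = s, is_single = res$is_single, k = res$k,
                             oversized = res$oversized)
    }
  }
  log$stages$splitting <- split_log

  counts <- count_report(structures, splits)
  nuclei <- do.call(rbind, lapply(seq_along(splits), function(s) {
    df <- splits[[s]]$nuclei
    df$structure_id <- s
    df
  }))
  radii_with <- nucleus_radial_positions(nuclei, geom)
  radii_without <- nucleus_radial_positions(
    do.call(rbind, lapply(structures, function(s) s$centroid)), geom)
  dist_with <- transmural_distribution(radii_with, config$density_bandwidth,
                                       config$grid_step)
  dist_without <- transmural_distribution(radii_without,
                                          config$density_bandwidth,
                                          config$grid_step)
  density <- medial_cell_density(radii_with, borders, green, geom)
  log$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  structure(list(geometry = geom, borders = borders, structures = structures,
                 splits = splits, counts = counts, nuclei = nuclei,
                 radii_with = radii_with, radii_without = radii_without,
                 distribution_with = dist_with,
                 distribution_without = dist_without, density = density,
                 stack_dim = dim(green$data), voxel_size = green$voxel_size,
                 log = log, config = config),
            class = "vessel_analysis")
}

#' @export
print.vessel_analysis <- function(x, ...) {
  cat("vessel_analysis\n")
  cat(sprintf("  centerline direction (%.3f, %.3f, %.3f), media [%.1f, %.1f] um\n",
              x$geometry$direction[1], x$geometry$direction[2],
              x$geometry$direction[3], x$borders$r_inner, x$borders$r_outer))
  cat(sprintf("  counts: %d without splitting, %d with splitting (%d multi-nucleus structures)\n",
              x$counts$count_without_splitting,
              x$counts$count_with_splitting, x$counts$n_multi))
  cat(sprintf("  medial density %.3g nuclei/mm^3 (%d nuclei in media)\n",
              x$density$medial_density_per_mm3, x$density$medial_count))
  invisible(x)
}

#' Per-voxel nucleus label map of an analysis
#'
#' Builds an integer 3D array in which every voxel of every extracted
#' structure carries the (global) id of the nucleus it was assigned to after
#' splitting; background voxels are zero.
#'
#' @param analysis A `vessel_analysis` from [run_pipeline()].
#' @return Integer 3D array with the stack's dimensions.
#' @export
label_map <- function(analysis) {
  stopifnot(inherits(analysis, "vessel_analysis"))
  labels <- array(0L, dim = analysis$stack_dim)
  offset <- 0L
  for (s in seq_along(analysis$structures)) {
    res <- analysis$splits[[s]]
    labels[analysis$structures[[s]]$voxels] <- offset + res$labels
    offset <- offset + res$k
  }
  labels
}

#' Write the main pipeline outputs to disk
#'
#' Writes counts and per-nucleus statistics as CSV, the transmural
#' distribution grids as CSV, the final nucleus label map as TIFF, and a
#' JSON summary (geometry, borders, counts, medial density) per stack.
#'
#' @param analysis A `vessel_analysis` from [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "vessel_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lm_ <- label_map(analysis)
  write_stack(image_stack(lm_, analysis$voxel_size, "nuclei",
                          intensity_max = max(1, max(lm_))),
              file.path(dir, "labels.tif"))
  utils::write.csv(analysis$nuclei, file.path(dir, "nuclei.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(analysis$distribution_with),
                   file.path(dir, "transmural_distribution_with.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(analysis$distribution_without),
                   file.path(dir, "transmural_distribution_without.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    centerline_point = analysis$geometry$point,
    centerline_direction = analysis$geometry$direction,
    r_inner = analysis$borders$r_inner, r_outer = analysis$borders$r_outer,
    count_without_splitting = analysis$counts$count_without_splitting,
    count_with_splitting = analysis$counts$count_with_splitting,
    medial_count = analysis$density$medial_count,
    media_volume_mm3 = analysis$density$media_volume_mm3,
    medial_density_per_mm3 = analysis$density$medial_density_per_mm3),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
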