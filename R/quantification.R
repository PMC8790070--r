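#' Radial positions of nuclei with respect to the vessel centerline
#'
#' Applies [radial_distance()] to nucleus centroids.
#'
#' @param centroids Numeric (n x 3) matrix of centroid positions (um), or a
#'   `nuclei` data frame from [split_structure()] results (columns x, y, z).
#' @param geom A fitted [vessel_geometry()].
#' @return Numeric vector of radii (um).
#' @export
nucleus_radial_positions <- function(centroids, geom) {
  if (is.data.frame(centroids))
    centroids <- as.matrix(centroids[, c("x", "y", "z")])
  radial_distance(centroids, geom)
}

#' Transmural cell-density distribution
#'
#' Gaussian kernel density of nucleus radial positions on a regular 0.1 um
#' grid (extended by four bandwidths beyond the data range so the normalized
#' density integrates to ~1). Both the normalized density and the
#' count-scaled density (`density * n`, whose area equals the nucleus count)
#' are returned.
#'
#' @param radii Numeric vector of nucleus radii (um), length >= 1.
#' @param bandwidth Kernel SD in um (default 1.0).
#' @param grid_step Grid resolution in um (default 0.1).
#' @return A data frame of class `transmural_distribution` with columns
#'   `radius`, `density` (normalized) and `count_density` (density * n);
#'   `n` and `bandwidth` are attached as attributes.
#' @export
transmural_distribution <- function(radii, bandwidth = 1.0, grid_step = 0.1) {
  if (length(radii) < 1L) stop("need at least one radius")
  dg <- .kde_grid(radii, bandwidth, grid_step)
  out <- data.frame(radius = dg$radius, density = dg$density,
                    count_density = dg$density * length(radii))
  attr(out, "n") <- length(radii)
  attr(out, "bandwidth") <- bandwidth
  class(out) <- c("transmural_distribution", "data.frame")
  out
}

#' @export
plot.transmural_distribution <- function(x, scaled = TRUE, ...) {
  y <- if (scaled) x$count_density else x$density
  plot(x$radius, y, type = "l", xlab = "radial location (um)",
       ylab = if (scaled) "nucleus density (count-scaled)"
       else "nucleus density (normalized)", ...)
  invisible(x)
}

#' Medial cell density
#'
#' The media volume is the number of stack voxels whose radial distance to
#' the vessel centerline lies within the media borders (closed interval),
#' times the voxel volume. The medial nucleus count applies the same radial
#' restriction to the nucleus centroids, and the density is their ratio,
#' reported per mm^3.
#'
#' @param radii Nucleus radial positions (um), see
#'   [nucleus_radial_positions()].
#' @param borders A [detect_media_borders()] result.
#' @param stack Any [image_stack()] of the scan (defines the voxel grid).
#' @param geom A fitted [vessel_geometry()].
#' @return A list of class `density_report`: `medial_count`,
#'   `media_volume_mm3`, `medial_density_per_mm3`, plus the borders used.
#' @export
medial_cell_density <- function(radii, borders, stack, geom) {
  stopifnot(inherits(borders, "media_borders"),
            inherits(stack, "image_stack"),
            inherits(geom, "vessel_geometry"))
  dims <- dim(stack$data)
  vs <- stack$voxel_size
  d1 <- ((seq_len(dims[1])) - 0.5) * vs[1] - geom$point[1]
  d2 <- ((seq_len(dims[2])) - 0.5) * vs[2] - geom$point[2]
  d3 <- ((seq_len(dims[3])) - 0.5) * vs[3] - geom$point[3]
  v <- geom$direction
  proj <- outer(outer(d1 * v[1], d2 * v[2], `+`), d3 * v[3], `+`)
  dsq <- outer(outer(d1^2, d2^2, `+`), d3^2, `+`)
  r <- sqrt(pmax(dsq - proj^2, 0))
  n_media_vox <- sum(r >= borders$r_inner & r <= borders$r_outer)
  vol_mm3 <- n_media_vox * prod(vs) * 1e-9   # um^3 -> mm^3
  count <- sum(radii >= borders$r_inner & radii <= borders$r_outer)
  structure(list(medial_count = count, media_volume_mm3 = vol_mm3,
                 medial_density_per_mm3 = count / vol_mm3,
                 borders = borders),
            class = "density_report")
}

#' @export
print.density_report <- function(x, ...) {
  cat(sprintf("density_report: %d medial nuclei in %.4g mm^3 media -> %.3g nuclei/mm^3 (%.2f x 10^4)\n",
              x$medial_count, x$media_volume_mm3, x$medial_density_per_mm3,
              x$medial_density_per_mm3 / 1e4))
  invisible(x)
}

#' Nucleus counts with and without splitting
#'
#' The count without splitting is the number of extracted structures; the
#' count with splitting sums the number of nuclei each structure was split
#' into.
#'
#' @param structures List from [extract_structures()].
#' @param split_results List of [split_structure()] results (one per
#'   structure).
#' @return List with `count_without_splitting`, `count_with_splitting`, and
#'   `n_multi` (structures recognized as multi-nucleus).
#' @export
count_report <- function(structures, split_results) {
  if (length(structures) != length(split_results))
    stop("one split result per structure is required")
  ks <- vapply(split_results, function(s) as.integer(s$k), integer(1))
  list(count_without_splitting = length(structures),
       count_with_splitting = sum(ks),
       n_multi = sum(ks > 1L))
}

#' Simple group-comparison report utilities
#'
#' Thin wrappers over standard routines for the statistical summaries that
#' accompany count results: a paired t-test between manual and automated
#' counts, a one-sample t-test of relative differences against zero, and a
#' linear regression of relative differences on the manual count. These are
#' conveniences, not part of the splitting method.
#'
#' @param manual,automated Numeric vectors of per-scan counts.
#' @return A list with the three fitted objects and the relative differences
#'   (in % of the manual count).
#' @export
count_comparison <- function(manual, automated) {
  stopifnot(length(manual) == length(automated))
  rel <- 100 * (automated - manual) / manual
  list(paired_t = stats::t.test(automated, manual, paired = TRUE),
       relative_t = stats::t.test(rel),
       regression = stats::lm(rel ~ manual),
       relative_diff_pct = rel)
}
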