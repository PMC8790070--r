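# Sampled Gaussian-derivative kernel in physical units. Tap positions are
# voxel centres; order-1/2 kernels are mean-corrected so derivatives of a
# constant image are exactly zero.
.gauss_kernel <- function(sigma, voxel, order = 0L) {
  half <- max(1L, round(3 * sigma / voxel))
  t <- (-half:half) * voxel
  g <- dnorm(t, sd = sigma) * voxel
  k <- switch(as.character(order),
    "0" = g / sum(g),
    "1" = {k <- -t / sigma^2 * g; k - mean(k)},
    "2" = {k <- (t^2 - sigma^2) / sigma^4 * g; k - mean(k)},
    stop("order must be 0, 1 or 2"))
  k
}

# Gaussian-smoothed Hessian of a 3D array by separable convolution in
# physical units (15 one-dimensional passes, sharing intermediates).
.hessian3d <- function(arr, voxel_size, sigma) {
  dims <- dim(arr)
  k0 <- lapply(1:3, function(a) .gauss_kernel(sigma, voxel_size[a], 0L))
  k1 <- lapply(1:3, function(a) .gauss_kernel(sigma, voxel_size[a], 1L))
  k2 <- lapply(1:3, function(a) .gauss_kernel(sigma, voxel_size[a], 2L))
  cv <- function(x, ker, axis) conv_axis_cpp(x, dims, ker, axis)

  A <- cv(arr, k0[[3]], 3L); B <- cv(arr, k1[[3]], 3L); C <- cv(arr, k2[[3]], 3L)
  A1 <- cv(A, k0[[2]], 2L); A2 <- cv(A, k1[[2]], 2L); A3 <- cv(A, k2[[2]], 2L)
  B1 <- cv(B, k0[[2]], 2L); B2 <- cv(B, k1[[2]], 2L)
  C1 <- cv(C, k0[[2]], 2L)
  list(xx = cv(A1, k2[[1]], 1L), xy = cv(A2, k1[[1]], 1L),
       yy = cv(A3, k0[[1]], 1L), xz = cv(B1, k1[[1]], 1L),
       yz = cv(B2, k0[[1]], 1L), zz = cv(C1, k0[[1]], 1L))
}

#' Single-scale 3D vesselness filter with orientation field
#'
#' Enhances bright elongated (tubular) structures with a Frangi-type
#' vesselness measure computed from the eigenvalues of the Gaussian-smoothed
#' Hessian at physical scale `sigma`. Second-order Gaussian-derivative
#' kernels are built per axis in voxel units (`sigma / voxel_size`),
#' truncated at +/-3 standard deviations, which for 0.2 x 0.2 x 0.45 um
#' voxels and `sigma = 1.2` um yields a 37 x 37 x 17 voxel kernel.
#'
#' With eigenvalues ordered `|l1| <= |l2| <= |l3|`, the response is zero
#' unless `l2 < 0` and `l3 < 0` (bright-on-dark polarity), and otherwise
#' `(1 - exp(-Ra^2 / 2 alpha^2)) * exp(-Rb^2 / 2 beta^2) *
#'  (1 - exp(-S^2 / 2 C^2))`
#' with `Ra = |l2| / |l3|`, `Rb = |l1| / sqrt(|l2 l3|)`,
#' `S = sqrt(l1^2 + l2^2 + l3^2)`, and `C = c * max(S)` (the sensitivity `c`
#' is interpreted as a fraction of the largest second-order structure norm in
#' the image, keeping it unitless). The response lies in `[0, 1]`.
#'
#' Each voxel is also assigned the eigenvector of the smallest-absolute
#' Hessian eigenvalue: inside an elongated nucleus this points along the
#' nucleus. Eigenvector signs are fixed (first non-zero component positive).
#'
#' @param stack An [image_stack()] (intensity-stretched nuclei channel).
#' @param sigma Gaussian scale in um (default 1.2).
#' @param alpha,beta,c Vesselness sensitivities (defaults all 0.15).
#' @return A list of class `vesselness_field`: `vesselness` (3D array in
#'   `[0, 1]`), `orientation` (list of arrays `ex`, `ey`, `ez`), and the
#'   parameters used.
#' @export
vesselness3d <- function(stack, sigma = 1.2, alpha = 0.15, beta = 0.15,
                         c = 0.15) {
  stopifnot(inherits(stack, "image_stack"))
  if (sigma < max(stack$voxel_size))
    stop(sprintf("sigma (%.3g um) is smaller than a voxel in some axis (max %.3g um)",
                 sigma, max(stack$voxel_size)))
  arr <- stack$data / stack$intensity_max
  H <- .hessian3d(arr, stack$voxel_size, sigma)
  eg <- hessian_eigen_cpp(H$xx, H$yy, H$zz, H$xy, H$xz, H$yz)
  rm(H)
  l1 <- eg$l1; l2 <- eg$l2; l3 <- eg$l3
  S2 <- l1^2 + l2^2 + l3^2
  smax2 <- max(S2)
  v <- numeric(length(l1))
  # S^2 floor: discard numerically-zero Hessians (flat image regions) so a
  # constant image maps to exactly zero response
  if (smax2 > 1e-16) {
    bright <- l2 < 0 & l3 < 0 & S2 > 1e-16
    Ra2 <- (l2[bright] / l3[bright])^2
    Rb2 <- l1[bright]^2 / abs(l2[bright] * l3[bright])
    C2 <- c^2 * smax2
    v[bright] <- (1 - exp(-Ra2 / (2 * alpha^2))) *
      exp(-Rb2 / (2 * beta^2)) *
      (1 - exp(-S2[bright] / (2 * C2)))
  }
  dims <- dim(stack$data)
  dim(v) <- dims
  orientation <- list(ex = array(eg$ex, dims), ey = array(eg$ey, dims),
                      ez = array(eg$ez, dims))
  structure(list(vesselness = v, orientation = orientation, sigma = sigma,
                 alpha = alpha, beta = beta, c = c,
                 voxel_size = stack$voxel_size),
            class = "vesselness_field")
}

#' @export
print.vesselness_field <- function(x, ...) {
  d <- dim(x$vesselness)
  cat(sprintf("vesselness_field: %d x %d x %d, sigma %.2f um, max response %.3f\n",
              d[1], d[2], d[3], x$sigma, max(x$vesselness)))
  invisible(x)
}

#' Segment nuclei from a vesselness map
#'
#' Thresholds the vesselness response (strictly greater than `threshold`)
#' into a binary nucleus mask.
#'
#' @param vness A `vesselness_field` from [vesselness3d()], or a numeric 3D
#'   array of vesselness values in `[0, 1]`.
#' @param threshold Intensity threshold (default 0.1).
#' @return Logical 3D array.
#' @export
segment_nuclei <- function(vness, threshold = 0.1) {
  v <- if (inherits(vness, "vesselness_field")) vness$vesselness else vness
  v > threshold
}

#' Extract connected nucleus structures from a binary mask
#'
#' Groups mask voxels into structures with a 3D 6-connectivity neighbourhood
#' connected-component analysis (face neighbours only, so voxels sharing only
#' an edge or corner are in different structures) and discards structures
#' whose volume is below `min_volume`. The number of surviving structures is
#' the automated cell count without nucleus splitting.
#'
#' @param mask Logical 3D array from [segment_nuclei()].
#' @param orientation Orientation field: the `orientation` element of a
#'   `vesselness_field` (or the whole field object).
#' @param voxel_size Voxel size in um (taken from the field when a
#'   `vesselness_field` is passed).
#' @param min_volume Minimum structure volume in um^3 (default 54); smaller
#'   structures are discarded, volumes exactly at the threshold are kept.
#' @return List of `nucleus_structure` objects, each with `id`, `voxels`
#'   (linear indices), `positions` (n x 3 um), `orientations` (n x 3 unit
#'   vectors), `centroid`, `volume` (um^3) and `voxel_volume`.
#' @export
extract_structures <- function(mask, orientation, voxel_size = NULL,
                               min_volume = 54) {
  if (inherits(orientation, "vesselness_field")) {
    if (is.null(voxel_size)) voxel_size <- orientation$voxel_size
    orientation <- orientation$orientation
  }
  if (is.null(voxel_size)) stop("`voxel_size` is required")
  dims <- dim(mask)
  labels <- label6_cpp(as.logical(mask), as.integer(dims))
  nz <- which(labels > 0L)
  if (length(nz) == 0L) return(list())
  voxvol <- prod(voxel_size)
  sizes <- tabulate(labels[nz])
  keep <- which(sizes * voxvol >= min_volume)
  if (length(keep) == 0L) return(list())
  groups <- split(nz, labels[nz])
  out <- vector("list", length(keep))
  for (s in seq_along(keep)) {
    vox <- groups[[as.character(keep[s])]]
    pos <- .stack_coords(vox, dims, voxel_size)
    ori <- cbind(orientation$ex[vox], orientation$ey[vox], orientation$ez[vox])
    out[[s]] <- structure(
      list(id = s, voxels = vox, positions = pos, orientations = ori,
           centroid = colMeans(pos), volume = length(vox) * voxvol,
           voxel_volume = voxvol),
      class = "nucleus_structure")
  }
  out
}

#' @export
print.nucleus_structure <- function(x, ...) {
  cat(sprintf("nucleus_structure %d: %d voxels, %.1f um^3, centroid (%.1f, %.1f, %.1f) um\n",
              x$id, length(x$voxels), x$volume,
              x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}
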