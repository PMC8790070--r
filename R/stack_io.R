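#' Calibrated 3D image stack
#'
#' Container for one channel of a 3D fluorescence image stack together with
#' its physical calibration. The data array is indexed `[x, y, z]`: `x` and
#' `y` span the image plane (the vessel runs along `y`) and `z` is the imaging
#' depth, increasing away from the objective. Voxel `[i, j, k]` is centred at
#' `((i - 0.5) * vx, (j - 0.5) * vy, (k - 0.5) * vz)` micrometres; this voxel
#' centre convention is used throughout the package.
#'
#' @param data Numeric 3D array of intensities, `dim = c(nx, ny, nz)`.
#' @param voxel_size Numeric length-3, voxel edge lengths in um (x, y, z).
#' @param channel `"nuclei"` or `"elastin"`.
#' @param intensity_max Maximum possible intensity value for the acquisition
#'   (e.g. 255 for 8-bit data, 1 for normalized data). Thresholds expressed as
#'   a percentage of the "maximum possible intensity" are taken relative to
#'   this value, not to the observed maximum.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, voxel_size, channel = c("nuclei", "elastin"),
                        intensity_max = 1) {
  channel <- match.arg(channel)
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array [x, y, z]")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be three strictly positive lengths (um)")
  if (!is.finite(intensity_max) || intensity_max <= 0)
    stop("`intensity_max` must be a positive scalar")
  mx <- max(data)
  if (mx > intensity_max * (1 + 1e-8))
    stop("observed intensities exceed `intensity_max`")
  structure(
    list(data = data, voxel_size = voxel_size, channel = channel,
         intensity_max = intensity_max),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  ext <- d * x$voxel_size
  cat(sprintf("image_stack [%s]: %d x %d x %d voxels (%.1f x %.1f x %.1f um)\n",
              x$channel, d[1], d[2], d[3], ext[1], ext[2], ext[3]))
  cat(sprintf("  voxel %.3g x %.3g x %.3g um, intensity range [%.3g, %.3g] of max %.3g\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              min(x$data), max(x$data), x$intensity_max))
  invisible(x)
}

#' Physical coordinates of voxel centres
#'
#' @param idx Integer matrix (n x 3) of 1-based voxel indices, or a vector of
#'   linear indices into the stack array.
#' @param stack An [image_stack()] (used for `dim` and `voxel_size`).
#' @return Numeric matrix (n x 3) of voxel-centre positions in um.
#' @export
voxel_centers <- function(idx, stack) {
  if (is.null(dim(idx)))
    idx <- arrayInd(as.integer(idx), dim(stack$data))
  sweep(idx - 0.5, 2L, stack$voxel_size, `*`)
}

# Linear stack index -> um coordinates without materialising arrayInd rownames
.stack_coords <- function(lin, dims, voxel_size) {
  idx <- arrayInd(lin, dims)
  sweep(idx - 0.5, 2L, voxel_size, `*`)
}

.meta_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write an image stack to TIFF with a calibration sidecar
#'
#' Writes a multi-page 32-bit float TIFF (one page per z slice, intensities
#' scaled to `[0, 1]` by `intensity_max`) plus a JSON sidecar
#' (`<stem>.json`) holding `voxel_size`, `channel` and `intensity_max`, so
#' that [read_stack()] round-trips the stack exactly.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  pages <- lapply(seq_len(d[3]), function(k)
    t(stack$data[, , k]) / stack$intensity_max)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(
    list(voxel_size = stack$voxel_size, channel = stack$channel,
         intensity_max = stack$intensity_max),
    .meta_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibrated image stack from TIFF
#'
#' Reads a (multi-page) TIFF written by [write_stack()] or by other software.
#' Calibration is taken from the JSON sidecar when present; otherwise
#' `voxel_size` must be supplied explicitly, and `intensity_max` defaults to
#' the maximum representable value of the file's integer bit depth (e.g. 255
#' for 8-bit). Missing calibration with no override is an error.
#'
#' @param path TIFF path.
#' @param voxel_size Optional explicit voxel size (um, length 3); overrides
#'   sidecar metadata.
#' @param channel Optional channel tag override (`"nuclei"` or `"elastin"`).
#' @param intensity_max Optional maximum possible intensity override.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, voxel_size = NULL, channel = NULL,
                       intensity_max = NULL) {
  if (!file.exists(path)) stop("cannot read stack: ", path)
  meta <- NULL
  mp <- .meta_path(path)
  if (file.exists(mp)) meta <- jsonlite::read_json(mp, simplifyVector = TRUE)

  if (is.null(voxel_size)) voxel_size <- meta$voxel_size
  if (is.null(voxel_size))
    stop("no voxel-size calibration for ", path,
         ": supply `voxel_size` or provide a metadata sidecar")
  if (is.null(channel)) channel <- if (!is.null(meta)) meta$channel else "nuclei"

  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bits <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- 8L
  is_float <- bits == 32L
  if (is.null(intensity_max)) {
    intensity_max <- if (!is.null(meta)) meta$intensity_max
    else if (is_float) 1 else 2^bits - 1
  }
  nx <- ncol(pages[[1]]); ny <- nrow(pages[[1]]); nz <- length(pages)
  arr <- array(0, dim = c(nx, ny, nz))
  # float pages hold the stored values scaled by intensity_max; integer
  # pages come back normalized to [0, 1] and are restored to raw counts
  scale <- if (is_float) intensity_max else 2^bits - 1
  for (k in seq_len(nz)) arr[, , k] <- t(pages[[k]]) * scale
  image_stack(arr, voxel_size, channel, intensity_max = intensity_max)
}

#' Contrast-stretch a stack so a lower intensity quantile spans the full range
#'
#' Linearly rescales intensities so that the `keep_fraction` quantile maps to
#' `intensity_max` and 0 maps to 0; values above the quantile are clipped to
#' `intensity_max`. With the default `keep_fraction = 0.996` the lowest 99.6%
#' of voxels (by intensity) span the whole intensity range, which suppresses
#' the influence of a few very bright voxels on subsequent global thresholds.
#' A constant stack is returned unchanged (with a message).
#'
#' @param stack An [image_stack()].
#' @param keep_fraction Quantile mapped to full scale, in (0, 1].
#' @return The stretched [image_stack()].
#' @export
stretch_intensity <- function(stack, keep_fraction = 0.996) {
  stopifnot(inherits(stack, "image_stack"))
  if (!is.finite(keep_fraction) || keep_fraction <= 0 || keep_fraction > 1)
    stop("`keep_fraction` must lie in (0, 1]")
  x <- stack$data
  if (max(x) <= min(x)) {
    message("stretch_intensity: constant image, returned unchanged")
    return(stack)
  }
  q <- quantile(x, keep_fraction, names = FALSE, type = 7)
  if (q <= 0) {
    message("stretch_intensity: non-positive quantile, returned unchanged")
    return(stack)
  }
  out <- pmin(x / q, 1) * stack$intensity_max
  stack$data <- out
  stack
}
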