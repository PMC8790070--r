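#' Specification of a synthetic vessel phantom
#'
#' Defines the geometry, optics and noise of a synthetic two-channel vessel
#' stack: a tilted cylindrical elastin shell (red channel) and elongated
#' ellipsoidal nuclei arranged in concentric layers within the wall (green
#' channel), with depth-dependent attenuation and additive noise. Defaults
#' emulate the imaging geometry of two-photon stacks of mouse carotid
#' arteries: 0.2 x 0.2 x 0.45 um voxels, nuclei 2-6 times longer than wide,
#' oriented in the circumferential-axial plane with a Normal helix-angle
#' spread.
#'
#' Layer radii follow `vessel_radius + (k - 0.5) * wall_thickness / n_layers`
#' for layer `k`. A fraction `touch_fraction` of the nuclei is placed as
#' fused pairs, either side by side within one layer (parallel, en echelon:
#' offset laterally in the tangent plane and staggered along the nucleus
#' axis) or radially stacked across adjacent layers, likewise staggered
#' (`pair_layer_ratio` sets the cross-layer share). Each fused pair is
#' connected by a dim fluorescent strand between the facing nucleus ends
#' (`link_radius`, `link_intensity`), emulating the off-target staining
#' material that links closely situated nuclei in real two-photon data and
#' makes them segment as a single structure. `pair_gap` (um between nominal
#' surfaces) and `pair_stagger` (fraction of the semi-length) control the
#' pair geometry.
#'
#' @param stack_shape Integer length-3, stack size in voxels (nx, ny, nz).
#' @param voxel_size Voxel size in um (x, y, z).
#' @param vessel_radius Inner media radius in um.
#' @param wall_thickness Media (wall) thickness in um.
#' @param centerline_tilt Tilt of the vessel axis away from the image y axis,
#'   degrees (split evenly between the x and z directions).
#' @param n_layers Number of concentric nucleus layers.
#' @param nuclei_per_layer Nuclei placed in each layer.
#' @param nucleus_axes Ellipsoid semi-axes in um (long, short, short); the
#'   long axis must be at least twice the short axes.
#' @param helix_angle_sd SD of the Normal helix-angle draw, degrees.
#' @param touch_fraction Fraction of nuclei placed as members of fused pairs,
#'   in `[0, 1]`.
#' @param pair_layer_ratio Fraction of fused pairs stacked radially across
#'   adjacent layers (the rest lie side by side within one layer).
#' @param pair_gap Range (um) of the surface gap of fused pairs, drawn
#'   uniformly.
#' @param pair_stagger Range of the longitudinal stagger of fused pairs, as
#'   a fraction of the nucleus semi-length.
#' @param link_radius,link_intensity Radius (um) and peak intensity of the
#'   dim strand connecting the members of a fused pair.
#' @param attenuation_length Depth decay constant in um (`Inf` disables
#'   attenuation).
#' @param noise List with `background_sd` and `signal_sd` (intensity units on
#'   a [0, 1] scale; the voxel noise SD is
#'   `background_sd + signal_sd * sqrt(I)`), or `NULL` for noise-free stacks.
#' @param edge_softness Width of the rendered intensity edges in um.
#' @param seed Integer seed controlling all randomness of the phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(stack_shape = c(256L, 320L, 112L),
                         voxel_size = c(0.2, 0.2, 0.45),
                         vessel_radius = 15,
                         wall_thickness = 8,
                         centerline_tilt = 5,
                         n_layers = 2L,
                         nuclei_per_layer = 30L,
                         nucleus_axes = c(6.5, 1.5, 1.5),
                         helix_angle_sd = 10,
                         touch_fraction = 0,
                         pair_layer_ratio = 0.5,
                         pair_gap = c(0.9, 1.4),
                         pair_stagger = c(0.9, 1.2),
                         link_radius = 1.2,
                         link_intensity = 0.8,
                         attenuation_length = 80,
                         noise = list(background_sd = 0.02, signal_sd = 0.05),
                         edge_softness = 0.1,
                         seed = 1L) {
  spec <- list(stack_shape = as.integer(stack_shape), voxel_size = voxel_size,
               vessel_radius = vessel_radius, wall_thickness = wall_thickness,
               centerline_tilt = centerline_tilt, n_layers = as.integer(n_layers),
               nuclei_per_layer = as.integer(nuclei_per_layer),
               nucleus_axes = nucleus_axes, helix_angle_sd = helix_angle_sd,
               touch_fraction = touch_fraction,
               pair_layer_ratio = pair_layer_ratio,
               pair_gap = pair_gap, pair_stagger = pair_stagger,
               link_radius = link_radius, link_intensity = link_intensity,
               attenuation_length = attenuation_length, noise = noise,
               edge_softness = edge_softness, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(stack_shape) != 3L || any(stack_shape < 8L))
      stop("`stack_shape` must be three voxel counts >= 8")
    if (any(voxel_size <= 0) || wall_thickness <= 0 || vessel_radius <= 0)
      stop("all phantom lengths must be positive")
    if (touch_fraction < 0 || touch_fraction > 1)
      stop("`touch_fraction` must lie in [0, 1]")
    if (length(nucleus_axes) != 3L || any(nucleus_axes <= 0))
      stop("`nucleus_axes` must be three positive semi-axes (um)")
    if (nucleus_axes[1] < 2 * max(nucleus_axes[2:3]))
      stop("nucleus long semi-axis must be >= 2x the short semi-axes")
    if (n_layers < 1L || nuclei_per_layer < 0L)
      stop("need at least one layer and a non-negative nucleus count")
  })
  # the full shell (plus its tilt excursion over the stack length) must fit
  # in the x-z cross-section
  ext <- spec$stack_shape * spec$voxel_size
  v <- .tilt_direction(spec$centerline_tilt)
  dev <- (ext[2] / 2) * abs(v[c(1, 3)]) / v[2]
  reach <- spec$vessel_radius + spec$wall_thickness + dev
  if (any(reach > c(ext[1], ext[3]) / 2))
    stop(sprintf(paste0(
      "vessel does not fit in the stack: shell reaches %.1f (x) / %.1f (z) um ",
      "from the centre but the stack allows only %.1f / %.1f um; enlarge ",
      "`stack_shape` or shrink `vessel_radius`/`wall_thickness`/tilt"),
      reach[1], reach[2], ext[1] / 2, ext[3] / 2))
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("phantom_spec: %d x %d x %d voxels, vessel r=%.1f um + ",
                     "%.1f um wall, tilt %.1f deg\n"),
              x$stack_shape[1], x$stack_shape[2], x$stack_shape[3],
              x$vessel_radius, x$wall_thickness, x$centerline_tilt))
  cat(sprintf("  %d layer(s) x %d nuclei, semi-axes (%.1f, %.1f, %.1f) um, touch %.0f%%\n",
              x$n_layers, x$nuclei_per_layer, x$nucleus_axes[1],
              x$nucleus_axes[2], x$nucleus_axes[3], 100 * x$touch_fraction))
  invisible(x)
}

.tilt_direction <- function(tilt_deg) {
  t <- tilt_deg * pi / 180
  v <- c(sin(t) / sqrt(2), cos(t), sin(t) / sqrt(2))
  v / sqrt(sum(v^2))
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# orthonormal frame with first axis u
.frame_from_axis <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u2 <- .unit(.cross3(u, ref))
  u3 <- .cross3(u, u2)
  cbind(u, u2, u3, deparse.level = 0)
}

#' Render a smooth-edged ellipsoid into an image stack
#'
#' Adds an ellipsoidal intensity blob (peak 1, sigmoidal edge of width
#' `edge_softness` um, half-maximum exactly on the ellipsoid surface) to the
#' stack, working in physical coordinates so voxel anisotropy is respected.
#' Existing intensities are combined by `max`, keeping values in `[0, 1]`.
#' A centre outside the stack leaves the stack unchanged; blobs partially
#' outside are clipped at the stack edge.
#'
#' @param center Ellipsoid centre, um.
#' @param orientation Unit vector of the long axis.
#' @param semi_axes Semi-axes in um (long, short, short).
#' @param stack An [image_stack()] to draw into.
#' @param edge_softness Edge width in um.
#' @return The modified [image_stack()].
#' @export
render_ellipsoid <- function(center, orientation, semi_axes, stack,
                             edge_softness = 0.1) {
  stopifnot(inherits(stack, "image_stack"))
  if (any(semi_axes <= 0)) stop("`semi_axes` must be positive")
  orientation <- .unit(orientation)
  stack$data <- .render_ellipsoid_into(stack$data, stack$voxel_size, center,
                                       orientation, semi_axes, edge_softness)
  stack
}

.render_ellipsoid_into <- function(arr, voxel_size, center, orientation,
                                   semi_axes, edge_softness, scale = 1) {
  dims <- dim(arr)
  ext <- dims * voxel_size
  if (any(center < 0) || any(center > ext)) return(arr)
  Rm <- .frame_from_axis(orientation)
  w <- edge_softness / min(semi_axes)            # edge width in m units
  # tight per-axis bounding half-widths of the (softened) ellipsoid support:
  # extent along coordinate axis i is sqrt(sum_j (R[i,j] a_j)^2)
  half <- sqrt(rowSums(sweep(Rm, 2L, semi_axes, `*`)^2)) * (1 + 8 * w) +
    voxel_size
  lo <- pmax(1L, floor((center - half) / voxel_size - 0.5) + 1L)
  hi <- pmin(dims, ceiling((center + half) / voxel_size + 0.5))
  if (any(lo > hi)) return(arr)
  xs <- ((lo[1]:hi[1]) - 0.5) * voxel_size[1] - center[1]
  ys <- ((lo[2]:hi[2]) - 0.5) * voxel_size[2] - center[2]
  zs <- ((lo[3]:hi[3]) - 0.5) * voxel_size[3] - center[3]
  # normalized ellipsoidal radius m: m = |diag(1/a) R^T d|
  msq <- array(0, dim = c(length(xs), length(ys), length(zs)))
  for (ax in 1:3) {
    q <- outer(outer(xs * Rm[1, ax], ys * Rm[2, ax], `+`), zs * Rm[3, ax], `+`)
    msq <- msq + (q / semi_axes[ax])^2
  }
  blob <- scale * stats::plogis((1 - sqrt(msq)) / w)
  blk <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- pmax(blk, blob)
  arr
}

# Render one nucleus bent along the vessel wall: the nucleus follows the
# helix through `center` with tangent direction given by the helix angle, on
# the cylinder of its own radius around the vessel centerline. Coordinates
# are computed on the unrolled cylinder (arc length s along the path, u
# transverse in the tangent surface, w radial), which is accurate to second
# order in the wall curvature. Cross-section stays ellipsoidal with
# semi-axes (b, c) and longitudinal semi-axis a.
.render_bent_nucleus <- function(arr, voxel_size, center, helix, axes,
                                 x0, vdir, edge) {
  dims <- dim(arr); ext <- dims * voxel_size
  if (any(center < 0) || any(center > ext)) return(arr)
  a <- axes[1]; b <- axes[2]; cc <- axes[3]
  half <- rep(a + max(b, cc) + 4 * edge, 3) + voxel_size
  lo <- pmax(1L, floor((center - half) / voxel_size - 0.5) + 1L)
  hi <- pmin(dims, ceiling((center + half) / voxel_size + 0.5))
  if (any(lo > hi)) return(arr)
  xs <- ((lo[1]:hi[1]) - 0.5) * voxel_size[1]
  ys <- ((lo[2]:hi[2]) - 0.5) * voxel_size[2]
  zs <- ((lo[3]:hi[3]) - 0.5) * voxel_size[3]
  # frame at the nucleus centre
  dc <- center - x0
  axc <- sum(dc * vdir)
  rc <- dc - axc * vdir
  r_n <- sqrt(sum(rc^2))
  rhat <- rc / r_n
  circ <- .unit(.cross3(vdir, rhat))
  # voxel coordinates in the orthonormal frame (vdir, rhat, circ) relative
  # to the centerline anchor, via separable outer sums
  d1 <- xs - x0[1]; d2 <- ys - x0[2]; d3 <- zs - x0[3]
  ax_coord <- outer(outer(d1 * vdir[1], d2 * vdir[2], `+`), d3 * vdir[3], `+`)
  S_r <- outer(outer(d1 * rhat[1], d2 * rhat[2], `+`), d3 * rhat[3], `+`)
  S_c <- outer(outer(d1 * circ[1], d2 * circ[2], `+`), d3 * circ[3], `+`)
  rho <- sqrt(S_r^2 + S_c^2)
  phi <- atan2(S_c, S_r)     # azimuth relative to the centre direction
  arcl <- r_n * phi          # unrolled circumferential coordinate
  dax <- ax_coord - axc      # axial coordinate
  ch <- cos(helix); sh <- sin(helix)
  s <- arcl * ch + dax * sh  # along the (helical) nucleus path
  u <- -arcl * sh + dax * ch # transverse, in the tangent surface
  w <- rho - r_n             # radial offset from the layer shell
  msq <- (s / a)^2 + (u / b)^2 + (w / cc)^2
  wdt <- edge / min(b, cc)
  blob <- stats::plogis((1 - sqrt(msq)) / wdt)
  blk <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- pmax(blk, blob)
  arr
}

# Dim connecting strand between the facing ends of a fused nucleus pair:
# a smooth Hermite arc from tip A to tip B rendered as a chain of small
# overlapping spheres, added at `intensity` times the blob profile.
.render_link <- function(arr, voxel_size, pA, eA, pB, eB, semi_len, radius,
                         intensity, edge) {
  dAB <- pB - pA
  sA <- if (sum(dAB * eA) >= 0) 1 else -1
  sB <- if (sum(dAB * eB) >= 0) 1 else -1
  tipA <- pA + eA * sA * (semi_len - 1)
  tipB <- pB - eB * sB * (semi_len - 1)
  m <- sqrt(sum((tipB - tipA)^2))
  if (m < 1e-6) return(arr)
  n <- max(8L, ceiling(m / 0.25))
  tt <- seq(0, 1, length.out = n)
  h00 <- 2 * tt^3 - 3 * tt^2 + 1; h10 <- tt^3 - 2 * tt^2 + tt
  h01 <- -2 * tt^3 + 3 * tt^2;    h11 <- tt^3 - tt^2
  pts <- h00 %o% tipA + h10 %o% (m * eA * sA) +
    h01 %o% tipB + h11 %o% (m * eB * sB)
  # the linking material is dimmest midway between the nuclei
  prof <- intensity * (1 - 0.3 * sin(pi * tt))
  dims <- dim(arr); ext <- dims * voxel_size
  w <- edge / radius
  pad <- radius * (1 + 8 * w) + voxel_size
  lo <- pmax(1L, floor((apply(pts, 2, min) - pad) / voxel_size - 0.5) + 1L)
  hi <- pmin(dims, ceiling((apply(pts, 2, max) + pad) / voxel_size + 0.5))
  if (any(lo > hi)) return(arr)
  xs <- ((lo[1]:hi[1]) - 0.5) * voxel_size[1]
  ys <- ((lo[2]:hi[2]) - 0.5) * voxel_size[2]
  zs <- ((lo[3]:hi[3]) - 0.5) * voxel_size[3]
  blk <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  for (i in seq_len(n)) {
    dsq <- outer(outer((xs - pts[i, 1])^2, (ys - pts[i, 2])^2, `+`),
                 (zs - pts[i, 3])^2, `+`)
    blob <- prof[i] * stats::plogis((1 - sqrt(dsq) / radius) / w)
    blk <- pmax(blk, blob)
  }
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- blk
  arr
}

# circumferential unit vector and outward radial at a point on the vessel
.local_frame <- function(p, x0, v) {
  d <- p - x0
  radial <- d - v * sum(v * d)
  rhat <- .unit(radial)
  circ <- .unit(.cross3(v, rhat))
  list(rhat = rhat, circ = circ)
}

#' Generate a synthetic two-channel vessel phantom with ground truth
#'
#' Renders the red (elastin shell) and green (nuclei) channels described by a
#' [phantom_spec()] and returns them together with a ground-truth table.
#' Nuclei are placed on jittered (angle, axial) grids per layer (layers are
#' staggered), oriented along the local circumferential direction rotated in
#' the tangent plane by a Normal helix angle. Fused pairs are created by
#' relocating a partner nucleus against its host, either side-by-side within
#' the layer or radially across layers. Intensities decay with imaging depth
#' as `exp(-z / attenuation_length)`; noise is additive Gaussian with a
#' signal-dependent (Poisson-like) term. Identical spec and seed give
#' bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom` with elements `red` and `green`
#'   ([image_stack()]s) and `truth` (a `phantom_truth` data frame with one
#'   row per nucleus: centroid, orientation, semi-axes, layer, fused partner;
#'   the true centerline and media borders are attached as attributes).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  dims <- spec$stack_shape
  vs <- spec$voxel_size
  ext <- dims * vs
  x0 <- c(ext[1] / 2, ext[2] / 2, ext[3] / 2)
  vdir <- .tilt_direction(spec$centerline_tilt)

  truth <- .place_nuclei(spec, x0, vdir, ext)

  green <- array(0, dim = dims)
  for (i in seq_len(nrow(truth))) {
    green <- .render_bent_nucleus(
      green, vs, c(truth$x[i], truth$y[i], truth$z[i]), truth$helix[i],
      c(truth$a1[i], truth$a2[i], truth$a3[i]), x0, vdir,
      spec$edge_softness)
  }
  for (i in seq_len(nrow(truth))) {
    j <- match(truth$fused_partner[i], truth$id)
    if (is.na(j) || j < i) next
    green <- .render_link(
      green, vs,
      c(truth$x[i], truth$y[i], truth$z[i]),
      c(truth$ox[i], truth$oy[i], truth$oz[i]),
      c(truth$x[j], truth$y[j], truth$z[j]),
      c(truth$ox[j], truth$oy[j], truth$oz[j]),
      spec$nucleus_axes[1], spec$link_radius, spec$link_intensity,
      spec$edge_softness)
  }
  red <- .render_shell(dims, vs, x0, vdir, spec$vessel_radius,
                       spec$wall_thickness, spec$edge_softness)

  zfac <- exp(-(((seq_len(dims[3])) - 0.5) * vs[3]) / spec$attenuation_length)
  for (k in seq_len(dims[3])) {
    green[, , k] <- green[, , k] * zfac[k]
    red[, , k] <- red[, , k] * zfac[k]
  }
  if (!is.null(spec$noise)) {
    green <- .apply_noise(green, spec$noise)
    red <- .apply_noise(red, spec$noise)
  }

  attr(truth, "centerline_point") <- x0
  attr(truth, "centerline_direction") <- vdir
  attr(truth, "r_inner") <- spec$vessel_radius
  attr(truth, "r_outer") <- spec$vessel_radius + spec$wall_thickness
  class(truth) <- c("phantom_truth", "data.frame")

  structure(list(
    red = image_stack(red, vs, "elastin", intensity_max = 1),
    green = image_stack(green, vs, "nuclei", intensity_max = 1),
    truth = truth, spec = spec), class = "phantom")
}

.render_shell <- function(dims, vs, x0, vdir, r_inner, wall, edge) {
  d1 <- ((seq_len(dims[1])) - 0.5) * vs[1] - x0[1]
  d2 <- ((seq_len(dims[2])) - 0.5) * vs[2] - x0[2]
  d3 <- ((seq_len(dims[3])) - 0.5) * vs[3] - x0[3]
  proj <- outer(outer(d1 * vdir[1], d2 * vdir[2], `+`), d3 * vdir[3], `+`)
  dsq <- outer(outer(d1^2, d2^2, `+`), d3^2, `+`)
  r <- sqrt(pmax(dsq - proj^2, 0))
  stats::plogis((r - r_inner) / edge) * stats::plogis((r_inner + wall - r) / edge)
}

.apply_noise <- function(arr, noise) {
  sdv <- noise$background_sd + noise$signal_sd * sqrt(pmax(arr, 0))
  pmin(pmax(arr + rnorm(length(arr)) * sdv, 0), 1)
}

# Jittered grid placement of nuclei on concentric layer shells, then fused
# pair creation by partner relocation.
.place_nuclei <- function(spec, x0, vdir, ext) {
  a <- spec$nucleus_axes[1]; b <- max(spec$nucleus_axes[2:3])
  spacing <- spec$wall_thickness / spec$n_layers
  hs <- spec$helix_angle_sd * pi / 180
  slot_arc <- 2 * a + 4
  slot_y <- 2 * b + 2 * a * sin(min(2 * hs, pi / 6)) + 1
  margin_y <- 2
  m_y <- max(1L, floor((ext[2] - 2 * margin_y) / slot_y))

  rows <- list()
  id <- 0L
  for (k in seq_len(spec$n_layers)) {
    r_k <- spec$vessel_radius + (k - 0.5) * spacing
    m_t <- max(1L, floor(2 * pi * r_k / slot_arc))
    cap <- m_t * m_y
    if (spec$nuclei_per_layer > cap)
      stop(sprintf(paste0("layer %d cannot hold %d nuclei (capacity %d); ",
                          "enlarge the stack or reduce `nuclei_per_layer`"),
                   k, spec$nuclei_per_layer, cap))
    slots <- sample(cap, spec$nuclei_per_layer)
    th_slot <- (slots - 1L) %% m_t
    y_slot <- (slots - 1L) %/% m_t
    stagger <- if (k %% 2L == 0L) 0.5 else 0
    for (s in seq_along(slots)) {
      theta <- (th_slot[s] + stagger + 0.5 + runif(1, -0.05, 0.05)) *
        (2 * pi / m_t)
      ypos <- margin_y + (y_slot[s] + 0.5) * slot_y + runif(1, -0.5, 0.5)
      id <- id + 1L
      rows[[id]] <- .make_nucleus(id, theta, ypos, r_k, k, x0, vdir, spec)
    }
  }
  if (id == 0L) {
    truth <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                        z = numeric(0), ox = numeric(0), oy = numeric(0),
                        oz = numeric(0), helix = numeric(0), a1 = numeric(0),
                        a2 = numeric(0), a3 = numeric(0), layer = integer(0),
                        fused_partner = integer(0))
    return(truth)
  }
  truth <- do.call(rbind, rows)
  truth$fused_partner <- NA_integer_
  attr(truth, "stack_extent") <- ext

  n <- nrow(truth)
  n_pairs <- round(spec$touch_fraction * n / 2)
  if (n_pairs > 0) {
    avail <- sample(n)
    for (p in seq_len(n_pairs)) {
      if (length(avail) < 2L) break
      placed <- FALSE
      # try hosts until the partner can be placed with full clearance
      for (h in seq_along(avail)) {
        host <- avail[h]
        partner <- avail[if (h == 1L) 2L else 1L]
        res <- .fuse_partner(truth, host, partner, x0, vdir, spec)
        if (attr(res, "clear")) {
          truth <- res
          avail <- avail[-c(h, if (h == 1L) 2L else 1L)]
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        # fall back to the first host with the best achievable layout
        host <- avail[1L]; partner <- avail[2L]
        truth <- .fuse_partner(truth, host, partner, x0, vdir, spec)
        avail <- avail[-(1:2)]
      }
    }
  }
  attr(truth, "stack_extent") <- NULL
  attr(truth, "clear") <- NULL
  truth
}

.make_nucleus <- function(id, theta, ypos, r_k, layer, x0, vdir, spec) {
  # position on the layer shell: start from the centerline point at axial
  # offset ypos, move radially by r_k in the direction given by theta
  fr <- .frame_from_axis(vdir)   # vdir, n1, n2 orthonormal
  axial <- ypos - x0[2]
  base <- x0 + vdir * axial / vdir[2]
  rhat <- cos(theta) * fr[, 2] + sin(theta) * fr[, 3]
  p <- base + rhat * r_k
  lf <- .local_frame(p, x0, vdir)
  helix <- rnorm(1, 0, spec$helix_angle_sd * pi / 180)
  e <- .unit(cos(helix) * lf$circ + sin(helix) * vdir)
  data.frame(id = id, x = p[1], y = p[2], z = p[3],
             ox = e[1], oy = e[2], oz = e[3], helix = helix,
             a1 = spec$nucleus_axes[1], a2 = spec$nucleus_axes[2],
             a3 = spec$nucleus_axes[3], layer = layer)
}

# sampled points along a nucleus axis segment
.axis_points <- function(p, e, a, n = 17L) {
  s <- seq(-a, a, length.out = n)
  cbind(p[1] + s * e[1], p[2] + s * e[2], p[3] + s * e[3])
}

# minimum distance between two sampled axis segments
.seg_dist <- function(pts1, pts2) {
  dsq <- outer(rowSums(pts1^2), rowSums(pts2^2), `+`) -
    2 * tcrossprod(pts1, pts2)
  sqrt(max(min(dsq), 0))
}

.fuse_partner <- function(truth, host, partner, x0, vdir, spec) {
  a <- spec$nucleus_axes[1]; b <- max(spec$nucleus_axes[2:3])
  hp <- c(truth$x[host], truth$y[host], truth$z[host])
  lf <- .local_frame(hp, x0, vdir)
  he <- c(truth$ox[host], truth$oy[host], truth$oz[host])
  others <- setdiff(seq_len(nrow(truth)), c(host, partner))
  other_pts <- lapply(others, function(i)
    .axis_points(c(truth$x[i], truth$y[i], truth$z[i]),
                 c(truth$ox[i], truth$oy[i], truth$oz[i]), a))
  clearance <- 2 * b + 2.0

  best <- NULL; best_clear <- -Inf
  for (attempt in 1:30) {
    cross_layer <- runif(1) < spec$pair_layer_ratio
    gap <- runif(1, spec$pair_gap[1], spec$pair_gap[2])
    stag <- runif(1, spec$pair_stagger[1], spec$pair_stagger[2]) *
      a * sample(c(-1, 1), 1)
    if (cross_layer) {
      # radially stacked: partner in the adjacent layer, staggered along
      # the host axis so the link connects near the nucleus ends
      outward <- truth$layer[host] < spec$n_layers || truth$layer[host] == 1L
      sgn <- if (outward) 1 else -1
      p <- hp + lf$rhat * sgn * (2 * b + gap) + he * stag
      new_layer <- truth$layer[host] + if (outward) 1L else -1L
    } else {
      # same layer: en-echelon neighbour, offset laterally in the tangent
      # plane and staggered along the host axis
      w <- .unit(vdir - he * sum(he * vdir))
      p <- hp + w * (2 * b + gap) * sample(c(-1, 1), 1) + he * stag
      new_layer <- truth$layer[host]
    }
    helix <- rnorm(1, 0, spec$helix_angle_sd * pi / 180)
    lf2 <- .local_frame(p, x0, vdir)
    e <- .unit(cos(helix) * lf2$circ + sin(helix) * vdir)
    cand_pts <- .axis_points(p, e, a)
    # approximate link path: straight chord between the facing tips
    dAB <- p - hp
    sA <- if (sum(dAB * he) >= 0) 1 else -1
    sB <- if (sum(dAB * e) >= 0) 1 else -1
    link_pts <- .axis_points((hp + he * sA * (a - 1) + p - e * sB * (a - 1)) / 2,
                             .unit(p - hp), sqrt(sum(dAB^2)) / 2, n = 9L)
    cl <- Inf
    for (op in other_pts) {
      cl <- min(cl, .seg_dist(cand_pts, op), .seg_dist(link_pts, op) + b - 0.8)
      if (cl < clearance) break
    }
    # keep the whole nucleus inside the stack
    ext <- attr(truth, "stack_extent")
    if (!is.null(ext)) {
      lo_ok <- all(sweep(cand_pts, 2L, rep(b + 0.5, 3)) >= 0)
      hi_ok <- all(sweep(-cand_pts, 2L, ext - (b + 0.5), `+`) >= 0)
      if (!lo_ok || !hi_ok) cl <- -Inf
    }
    if (cl > best_clear) {
      best_clear <- cl
      best <- list(p = p, e = e, helix = helix, layer = new_layer)
    }
    if (cl >= clearance) break
  }
  truth$x[partner] <- best$p[1]; truth$y[partner] <- best$p[2]
  truth$z[partner] <- best$p[3]
  truth$ox[partner] <- best$e[1]; truth$oy[partner] <- best$e[2]
  truth$oz[partner] <- best$e[3]
  truth$helix[partner] <- best$helix
  truth$layer[partner] <- best$layer
  truth$fused_partner[host] <- truth$id[partner]
  truth$fused_partner[partner] <- truth$id[host]
  attr(truth, "clear") <- best_clear >= clearance
  truth
}

# radial distance of a point from the centerline through x0 along vdir
radius_of <- function(p, x0, vdir) {
  d <- p - x0
  sqrt(max(sum(d^2) - sum(vdir * d)^2, 0))
}

#' @export
print.phantom <- function(x, ...) {
  cat("vessel phantom\n")
  print(x$spec)
  n <- nrow(x$truth)
  cat(sprintf("  %d nuclei (%d in fused pairs)\n", n,
              sum(!is.na(x$truth$fused_partner))))
  invisible(x)
}

#' Write a phantom to disk
#'
#' Writes the two channels as calibrated TIFF stacks (`red.tif`,
#' `green.tif`), the ground truth as CSV (`truth.csv`, one row per nucleus)
#' and the true geometry as JSON (`geometry.json`).
#'
#' @param phantom A `phantom` from [generate_phantom()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stack(phantom$red, file.path(dir, "red.tif"))
  write_stack(phantom$green, file.path(dir, "green.tif"))
  utils::write.csv(as.data.frame(phantom$truth),
                   file.path(dir, "truth.csv"), row.names = FALSE)
  tr <- phantom$truth
  jsonlite::write_json(
    list(centerline_point = attr(tr, "centerline_point"),
         centerline_direction = attr(tr, "centerline_direction"),
         r_inner = attr(tr, "r_inner"), r_outer = attr(tr, "r_outer")),
    file.path(dir, "geometry.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
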