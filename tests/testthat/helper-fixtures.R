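# Shared fixtures, built lazily once per test run. The "small" phantom is a
# compact vessel with 8 nuclei, one fused pair, realistic noise; expensive
# stages (vesselness, extraction, splitting) are cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

small_phantom_spec <- function(...) {
  phantom_spec(stack_shape = c(256L, 144L, 112L), nuclei_per_layer = 4L,
               touch_fraction = 0.25, seed = 4L, ...)
}

small_phantom <- function() {
  fixture("small_phantom", function() generate_phantom(small_phantom_spec()))
}

small_analysis <- function() {
  fixture("small_analysis", function() {
    ph <- small_phantom()
    vf <- vesselness3d(stretch_intensity(ph$green))
    mask <- segment_nuclei(vf)
    structures <- extract_structures(mask, vf)
    geom <- fit_centerline(stretch_intensity(ph$red))
    splits <- lapply(seq_along(structures), function(s)
      split_structure(structures[[s]], geom, seed = 100L + s))
    list(phantom = ph, field = vf, mask = mask, structures = structures,
         geom = geom, splits = splits)
  })
}

# bare elastin shell (no nuclei), noise-free, no attenuation
shell_phantom <- function(tilt = 5, noise = NULL, seed = 21L) {
  spec <- phantom_spec(stack_shape = c(224L, 128L, 112L), vessel_radius = 12,
                       wall_thickness = 6, centerline_tilt = tilt,
                       nuclei_per_layer = 0L, noise = noise,
                       attenuation_length = Inf, seed = seed)
  generate_phantom(spec)
}

# angle between two axial (sign-free) unit vectors, degrees
axis_angle_deg <- function(u, v) {
  acos(min(abs(sum(u * v) / sqrt(sum(u^2) * sum(v^2))), 1)) * 180 / pi
}

# random unit vector
runit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# independent connected-components oracle on a similarity matrix (BFS)
components_oracle <- function(R) {
  n <- nrow(R)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(R[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# map each structure to the truth nuclei it contains (centres within 2 um of
# a structure voxel)
truth_in_structure <- function(structure, truth) {
  tc <- as.matrix(truth[, c("x", "y", "z")])
  hits <- apply(tc, 1, function(p)
    min(colSums((t(structure$positions) - p)^2)) < 4)
  truth$id[hits]
}
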