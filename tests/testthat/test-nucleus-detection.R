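test_that("a constant image has zero vesselness everywhere", {
  st <- image_stack(array(0.7, dim = c(32, 32, 16)), c(0.2, 0.2, 0.45),
                    "nuclei")
  vf <- vesselness3d(st)
  expect_true(all(vf$vesselness == 0))
})

test_that("a sub-voxel scale is rejected", {
  st <- image_stack(array(0, dim = c(16, 16, 8)), c(0.2, 0.2, 0.45), "nuclei")
  expect_error(vesselness3d(st, sigma = 0.3), "smaller than a voxel")
})

test_that("orientations on a bright cylinder follow the cylinder axis", {
  st <- image_stack(array(0, dim = c(96, 48, 48)), c(0.2, 0.2, 0.45), "nuclei")
  st <- render_ellipsoid(c(9.6, 4.8, 10.8), c(1, 0, 0), c(8, 1.2, 1.2), st)
  vf <- vesselness3d(st)
  # axis voxels: along the centre line, away from the tips
  ix <- seq(20, 76, by = 4)
  iy <- round(4.8 / 0.2 + 0.5); iz <- round(10.8 / 0.45 + 0.5)
  for (i in ix) {
    e <- c(vf$orientation$ex[i, iy, iz], vf$orientation$ey[i, iy, iz],
           vf$orientation$ez[i, iy, iz])
    expect_lt(axis_angle_deg(e, c(1, 0, 0)), 5)
  }
})

test_that("cylinders out-score spheres of equal peak intensity", {
  st <- image_stack(array(0, dim = c(96, 64, 48)), c(0.2, 0.2, 0.45), "nuclei")
  st <- render_ellipsoid(c(5, 4, 10.8), c(1, 0, 0), c(6, 1.2, 1.2), st)
  st <- render_ellipsoid(c(14, 9, 10.8), c(1, 0, 0), c(1.6, 1.6, 1.6), st)
  vf <- vesselness3d(st)
  dims <- dim(vf$vesselness)
  pos <- vesselnuclei:::.stack_coords(seq_len(prod(dims)), dims,
                                      st$voxel_size)
  # compare the cylinder axis against the sphere centre (the blob-rejection
  # term suppresses the sphere's core)
  on_axis <- abs(pos[, 2] - 4) < 0.4 & abs(pos[, 3] - 10.8) < 0.4 &
    abs(pos[, 1] - 5) < 4
  at_centre <- sqrt((pos[, 1] - 14)^2 + (pos[, 2] - 9)^2 +
                      (pos[, 3] - 10.8)^2) < 0.7
  expect_gt(max(vf$vesselness[on_axis]), max(vf$vesselness[at_centre]))
})

test_that("vesselness commutes with 90-degree rotation on isotropic voxels", {
  set.seed(3)
  st <- image_stack(array(0, dim = c(48, 48, 48)), c(0.3, 0.3, 0.3), "nuclei")
  st <- render_ellipsoid(c(7.2, 6, 7.2), c(1, 1, 0) / sqrt(2), c(3, 0.9, 0.9), st)
  vf1 <- vesselness3d(st, sigma = 1.2)
  rot <- st
  rot$data <- aperm(st$data, c(2, 1, 3))[48:1, , ]   # 90 deg about z
  vf2 <- vesselness3d(rot, sigma = 1.2)
  back <- aperm(vf2$vesselness[48:1, , ], c(2, 1, 3))
  core <- 10:38
  expect_equal(vf1$vesselness[core, core, core], back[core, core, core],
               tolerance = 1e-6)
})

test_that("segmentation thresholds strictly", {
  expect_equal(sum(segment_nuclei(array(0, dim = c(4, 4, 4)))), 0)
  expect_equal(sum(segment_nuclei(array(0.1, dim = c(4, 4, 4)), 0.1)), 0)
  expect_equal(sum(segment_nuclei(array(0.11, dim = c(4, 4, 4)), 0.1)), 64)
})

test_that("6-connectivity separates corner-touching blobs", {
  mask <- array(FALSE, dim = c(8, 8, 4))
  mask[2:3, 2:3, 2] <- TRUE
  mask[4:5, 4:5, 2] <- TRUE     # shares only an edge/corner with the first
  ori <- list(ex = array(1, dim(mask)), ey = array(0, dim(mask)),
              ez = array(0, dim(mask)))
  st <- extract_structures(mask, ori, c(0.2, 0.2, 0.45), min_volume = 0)
  expect_length(st, 2L)
})

test_that("the minimum volume threshold is applied in physical units", {
  # voxel volume 0.018 um^3: 2999 voxels = 53.98 um^3 (discarded),
  # 3001 voxels = 54.02 um^3 (kept)
  mk <- function(n) {
    dims <- c(40L, 40L, 8L)
    mask <- array(FALSE, dims)
    mask[seq_len(n) - 1L + 1L] <- FALSE
    # snake-fill the first n voxels of a 40x40xk block (6-connected)
    filled <- 0L
    for (k in 1:8) for (j in 1:40) {
      cols <- if (j %% 2 == 1) 1:40 else 40:1
      for (i in cols) {
        if (filled >= n) break
        mask[i, j, k] <- TRUE
        filled <- filled + 1L
      }
    }
    ori <- list(ex = array(1, dims), ey = array(0, dims), ez = array(0, dims))
    extract_structures(mask, ori, c(0.2, 0.2, 0.45), min_volume = 54)
  }
  expect_length(mk(2999L), 0L)
  kept <- mk(3001L)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$volume, 3001 * 0.018)
})

test_that("extracted structures partition the large-enough mask", {
  an <- small_analysis()
  all_vox <- sort(unlist(lapply(an$structures, `[[`, "voxels")))
  expect_equal(anyDuplicated(all_vox), 0L)
  # union equals the mask voxels of the surviving components
  labels <- vesselnuclei:::label6_cpp(an$mask, dim(an$mask))
  keep_sizes <- table(labels[labels > 0])
  keep <- as.integer(names(keep_sizes))[keep_sizes * 0.018 >= 54]
  expect_setequal(all_vox, which(labels %in% keep))
})

test_that("the mask covers the cores of the rendered nuclei", {
  an <- small_analysis()
  tr <- an$phantom$truth
  dims <- dim(an$mask)
  # core sample points: voxels within half the semi-axes of each centroid
  covered <- vapply(seq_len(nrow(tr)), function(i) {
    ctr <- round(c(tr$x[i] / 0.2, tr$y[i] / 0.2, tr$z[i] / 0.45) + 0.5)
    an$mask[ctr[1], ctr[2], ctr[3]]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("orientation field aligns with the true axis inside nuclei", {
  spec <- phantom_spec(stack_shape = c(224L, 128L, 112L), vessel_radius = 12,
                       wall_thickness = 6, nuclei_per_layer = 2L,
                       noise = NULL, attenuation_length = Inf, seed = 13L)
  ph <- generate_phantom(spec)
  vf <- vesselness3d(stretch_intensity(ph$green))
  mask <- segment_nuclei(vf)
  tr <- ph$truth
  ok <- 0L; tot <- 0L
  for (i in seq_len(nrow(tr))) {
    ctr <- c(tr$x[i], tr$y[i], tr$z[i])
    axis <- c(tr$ox[i], tr$oy[i], tr$oz[i])
    # sample along the central third of the nucleus
    for (s in seq(-tr$a1[i] / 3, tr$a1[i] / 3, length.out = 7)) {
      p <- ctr + s * axis
      v <- round(c(p[1] / 0.2, p[2] / 0.2, p[3] / 0.45) + 0.5)
      if (!mask[v[1], v[2], v[3]]) next
      e <- c(vf$orientation$ex[v[1], v[2], v[3]],
             vf$orientation$ey[v[1], v[2], v[3]],
             vf$orientation$ez[v[1], v[2], v[3]])
      tot <- tot + 1L
      if (axis_angle_deg(e, axis) < 10) ok <- ok + 1L
    }
  }
  expect_gte(ok / tot, 0.8)
})
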