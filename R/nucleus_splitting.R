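#' Parameters of the nucleus splitting procedure
#'
#' Bundles the tunable constants of the three splitting steps. Defaults are
#' the published values for vascular smooth muscle cell nuclei: `sigma_r`
#' (0.8 um) reflects the width and `sigma_td` (0.8 um) the transmural
#' thickness of a nucleus; `d_min = 40` is the absolute summed-similarity
#' degree below which voxels are excluded from spectral clustering;
#' structures whose included volume is below `single_min_volume` (1.8 um^3)
#' are single nuclei by fiat; the Laplacian eigenvalue rule declares a single
#' nucleus when the first eigenvalue is below `lambda1_max` (0.01) and the
#' second above `lambda2_min` (0.02); k-means is restarted `n_restarts` (20)
#' times for each candidate number of cores up to `k_max` (10); excluded
#' voxels are assigned to cores with `sigma_vc` (2 um) and `sigma_vs` (5 um);
#' cores of at most `small_core_voxels` (12) voxels use the mean orientation
#' as their centerline.
#'
#' The remaining entries are numerical controls: pairs with similarity below
#' `rho_cutoff` are dropped from the sparse affinity graph; the mean
#' silhouette is estimated on at most `silhouette_sample` embedded voxels;
#' structures above `max_voxels` voxels are reported as oversized rather
#' than split; `eigs_tol` is the Lanczos convergence tolerance.
#'
#' @param sigma_r,sigma_td Likelihood SDs in um.
#' @param d_min Degree threshold for inclusion in the Laplacian.
#' @param single_min_volume Included-volume floor in um^3 for the
#'   single-nucleus shortcut.
#' @param lambda1_max,lambda2_min Eigenvalue thresholds of the single-nucleus
#'   rule.
#' @param k_max Maximum number of cores per structure.
#' @param n_restarts k-means restarts per candidate k.
#' @param sigma_vc,sigma_vs Assignment SDs in um.
#' @param small_core_voxels Voxel-count threshold for the mean-orientation
#'   centerline rule.
#' @param rho_cutoff,silhouette_sample,max_voxels,eigs_tol Numerical
#'   controls, see Details.
#' @return An object of class `split_params`.
#' @export
split_params <- function(sigma_r = 0.8, sigma_td = 0.8, d_min = 40,
                         single_min_volume = 1.8, lambda1_max = 0.01,
                         lambda2_min = 0.02, k_max = 10L, n_restarts = 20L,
                         sigma_vc = 2, sigma_vs = 5, small_core_voxels = 12L,
                         rho_cutoff = 1e-6, silhouette_sample = 2000L,
                         max_voxels = 150000L, eigs_tol = 1e-5) {
  if (sigma_r <= 0 || sigma_td <= 0 || sigma_vc <= 0 || sigma_vs <= 0)
    stop("all likelihood standard deviations must be positive")
  structure(list(sigma_r = sigma_r, sigma_td = sigma_td, d_min = d_min,
                 single_min_volume = single_min_volume,
                 lambda1_max = lambda1_max, lambda2_min = lambda2_min,
                 k_max = as.integer(k_max), n_restarts = as.integer(n_restarts),
                 sigma_vc = sigma_vc, sigma_vs = sigma_vs,
                 small_core_voxels = as.integer(small_core_voxels),
                 rho_cutoff = rho_cutoff,
                 silhouette_sample = as.integer(silhouette_sample),
                 max_voxels = as.integer(max_voxels), eigs_tol = eigs_tol),
            class = "split_params")
}

#' Collinearity likelihood of a voxel pair
#'
#' Likelihood that two voxels belong to the same elongated structure, from
#' the shortest distance `r_ij` of voxel i to the line through voxel j along
#' j's orientation and vice versa:
#' `exp(-(r_ij^2 + r_ji^2) / (2 sigma_r^2))`. High when the voxels are close
#' together regardless of orientation, and also when they are far apart but
#' positions and orientations are in line (opposite ends of one nucleus).
#' Symmetric in the pair and invariant to flipping either orientation.
#'
#' @param xi,xj Voxel positions (um).
#' @param ei,ej Unit orientation vectors.
#' @param sigma_r SD in um (default 0.8).
#' @return Likelihood in `[0, 1]`.
#' @export
axis_likelihood <- function(xi, ei, xj, ej, sigma_r = 0.8) {
  d <- xi - xj
  rij2 <- max(sum(d^2) - sum(d * ej)^2, 0)
  rji2 <- max(sum(d^2) - sum(d * ei)^2, 0)
  exp(-(rij2 + rji2) / (2 * sigma_r^2))
}

#' Transmural-distance likelihood of a voxel pair
#'
#' Likelihood that two voxels lie in the same cell layer:
#' `exp(-d_td^2 / (2 sigma_td^2))` with `d_td` the projection of the
#' voxel-pair separation onto the transmural direction of the structure.
#'
#' @param xi,xj Voxel positions (um).
#' @param vtm Transmural vector (centerline to structure centroid); need not
#'   be normalized but must be non-zero.
#' @param sigma_td SD in um (default 0.8).
#' @return Likelihood in `[0, 1]`.
#' @export
transmural_likelihood <- function(xi, xj, vtm, sigma_td = 0.8) {
  vn <- sqrt(sum(vtm^2))
  if (vn <= 0) stop("transmural vector has zero length")
  dtd <- abs(sum(vtm * (xi - xj))) / vn
  exp(-dtd^2 / (2 * sigma_td^2))
}

#' In-plane orientation likelihood of a voxel pair
#'
#' `(1 - |vhat_tm . e_i|) (1 - |vhat_tm . e_j|)`: high only when both voxel
#' orientations lie essentially in the circumferential-axial plane of the
#' vessel (perpendicular to the transmural direction). Transmurally oriented
#' voxels - typically bridges between touching nuclei of different layers -
#' receive low values, which in the affinity graph demotes them to low
#' degrees and excludes them from core finding.
#'
#' @param ei,ej Unit orientation vectors.
#' @param vtm Transmural vector (non-zero).
#' @return Likelihood in `[0, 1]`.
#' @export
plane_likelihood <- function(ei, ej, vtm) {
  vhat <- .unit(vtm)
  max(1 - abs(sum(vhat * ei)), 0) * max(1 - abs(sum(vhat * ej)), 0)
}

#' Build the voxel-pair affinity graph of a structure
#'
#' Computes the pairwise similarity `rho_ij = p_rd * p_ta * p_td` (product of
#' [axis_likelihood()], [plane_likelihood()] and [transmural_likelihood()])
#' for all voxel pairs of a structure, with zero diagonal, using the
#' transmural direction from the vessel centerline to the structure centroid.
#' Pairs below `rho_cutoff` are dropped (sparse storage). Voxel degrees
#' `d_i = sum_j rho_ij` are computed over the whole structure; voxels with
#' `d_i < d_min` are excluded from the Laplacian (they are re-assigned to
#' cores later). Degrees are recomputed on the included subset so that the
#' rows of `D^-1 R` sum to one there; included voxels left isolated by the
#' restriction are moved to the excluded set.
#'
#' @param structure A `nucleus_structure` from [extract_structures()].
#' @param geom A fitted [vessel_geometry()].
#' @param params A [split_params()].
#' @return An object of class `affinity_graph`.
#' @export
build_affinity <- function(structure, geom, params = split_params()) {
  stopifnot(inherits(structure, "nucleus_structure"),
            inherits(geom, "vessel_geometry"))
  n <- nrow(structure$positions)
  if (n < 2L) stop("structure must have at least 2 voxels")
  xc <- structure$centroid
  d <- xc - geom$point
  vtm <- d - geom$direction * sum(geom$direction * d)
  if (sqrt(sum(vtm^2)) < 1e-9)
    stop("structure centroid lies on the vessel centerline; transmural direction undefined")
  tri <- affinity_pairs_cpp(structure$positions, structure$orientations,
                            vtm, params$sigma_r, params$sigma_td,
                            params$rho_cutoff)
  .affinity_graph(tri$i, tri$j, tri$x, tri$degree, n, params$d_min,
                  structure$voxel_volume, vtm)
}

# shared constructor: restrict to the included set, recomputing sub-degrees
# and dropping voxels isolated by the restriction
.affinity_graph <- function(ti, tj, tx, degree, n, d_min, voxel_volume, vtm) {
  included <- which(degree >= d_min)
  sub_i <- integer(0); sub_j <- integer(0); sub_x <- numeric(0)
  sub_deg <- numeric(0)
  repeat {
    if (length(included) == 0L) break
    inc <- logical(n); inc[included] <- TRUE
    keep <- inc[ti] & inc[tj]
    map <- integer(n); map[included] <- seq_along(included)
    sub_i <- map[ti[keep]]; sub_j <- map[tj[keep]]; sub_x <- tx[keep]
    sub_deg <- numeric(length(included))
    if (length(sub_x) > 0L) {
      acc <- rowsum(c(sub_x, sub_x), c(sub_i, sub_j))
      sub_deg[as.integer(rownames(acc))] <- acc[, 1]
    }
    if (all(sub_deg > 0)) break
    included <- included[sub_deg > 0]
  }
  structure(list(n = n, trip_i = ti, trip_j = tj, trip_x = tx,
                 degrees = degree, included = included,
                 sub_i = sub_i, sub_j = sub_j, sub_x = sub_x,
                 sub_degrees = sub_deg, d_min = d_min,
                 voxel_volume = voxel_volume, vtm = vtm),
            class = "affinity_graph")
}

#' Construct an affinity graph from an explicit similarity matrix
#'
#' Mainly for testing and for spectral-clustering experiments on synthetic
#' graphs: takes a symmetric similarity matrix with zero diagonal and builds
#' the same `affinity_graph` object as [build_affinity()].
#'
#' @param R Symmetric numeric matrix, entries in `[0, 1]`, zero diagonal.
#' @param d_min Degree threshold.
#' @param voxel_volume Volume of one voxel (um^3).
#' @return An `affinity_graph`.
#' @export
affinity_graph_from_matrix <- function(R, d_min = 40,
                                       voxel_volume = prod(c(0.2, 0.2, 0.45))) {
  if (!isSymmetric(unname(R))) stop("R must be symmetric")
  if (any(diag(R) != 0)) stop("R must have a zero diagonal")
  n <- nrow(R)
  up <- which(upper.tri(R) & R > 0, arr.ind = TRUE)
  .affinity_graph(up[, 1], up[, 2], R[up], rowSums(R), n, d_min,
                  voxel_volume, vtm = c(0, 0, 1))
}

#' Dense similarity matrix of an affinity graph
#'
#' @param graph An `affinity_graph`.
#' @param included_only Return only the included-voxel submatrix.
#' @return Symmetric numeric matrix.
#' @export
affinity_matrix <- function(graph, included_only = FALSE) {
  stopifnot(inherits(graph, "affinity_graph"))
  if (included_only) {
    m <- length(graph$included)
    R <- matrix(0, m, m)
    R[cbind(graph$sub_i, graph$sub_j)] <- graph$sub_x
  } else {
    R <- matrix(0, graph$n, graph$n)
    R[cbind(graph$trip_i, graph$trip_j)] <- graph$trip_x
  }
  R + t(R)
}

#' @export
print.affinity_graph <- function(x, ...) {
  cat(sprintf("affinity_graph: %d voxels, %d of them included (d >= %g), %d stored pairs\n",
              x$n, length(x$included), x$d_min, length(x$trip_x)))
  invisible(x)
}

# dense eigenpairs of L_rw via the symmetric normalized Laplacian
.dense_spectrum <- function(graph, k) {
  m <- length(graph$included)
  R <- matrix(0, m, m)
  R[cbind(graph$sub_i, graph$sub_j)] <- graph$sub_x
  R <- R + t(R)
  dis <- 1 / sqrt(graph$sub_degrees)
  Lsym <- diag(m) - (dis * R) * rep(dis, each = m)
  ee <- eigen(Lsym, symmetric = TRUE)
  idx <- m:(m - k + 1L)
  vectors <- ee$vectors[, idx, drop = FALSE] * dis
  vectors <- sweep(vectors, 2L, sqrt(colSums(vectors^2)), `/`)
  list(values = ee$values[idx], vectors = vectors)
}

# k smallest-absolute eigenpairs of L_rw on the included subgraph.
# Dense solve for small graphs, Lanczos on the shifted symmetric form
# otherwise; eigenvector signs are fixed for reproducibility.
.graph_spectrum <- function(graph, k, params = split_params()) {
  m <- length(graph$included)
  if (m < 2L) stop("need at least 2 included voxels for a spectrum")
  k <- min(k, m - 1L)
  if (m <= 400L) {
    sp <- .dense_spectrum(graph, k)
  } else {
    sp <- lrw_spectrum_cpp(graph$sub_i, graph$sub_j, graph$sub_x, m, k,
                           params$eigs_tol)
    if (is.null(sp)) {
      if (m <= 4000L) sp <- .dense_spectrum(graph, k)
      else stop("Lanczos eigensolver failed to converge on a graph too large for a dense solve")
    }
  }
  values <- sp$values
  vectors <- sp$vectors
  for (c in seq_len(ncol(vectors))) {
    pivot <- which.max(abs(vectors[, c]))
    if (vectors[pivot, c] < 0) vectors[, c] <- -vectors[, c]
  }
  list(values = values, vectors = vectors)
}

#' Single-nucleus test for an affinity graph
#'
#' A structure is deemed a single nucleus when the total volume of its
#' included voxels is below `single_min_volume` (too few voxels to support
#' several cores), or when the first and second smallest-absolute eigenvalues
#' of the random-walk Laplacian satisfy `lambda1 < lambda1_max` and
#' `lambda2 > lambda2_min` (all voxels sufficiently likely to belong to one
#' nucleus). A second eigenvalue in the ambiguous band between the two
#' thresholds proceeds to clustering.
#'
#' @param graph An `affinity_graph`.
#' @param params A [split_params()].
#' @param spectrum Optional precomputed spectrum from an internal call, to
#'   avoid recomputation.
#' @return Logical; the eigenvalues used (if any) are attached as attribute
#'   `eigenvalues`.
#' @export
is_single_nucleus <- function(graph, params = split_params(),
                              spectrum = NULL) {
  stopifnot(inherits(graph, "affinity_graph"))
  m <- length(graph$included)
  if (m * graph$voxel_volume < params$single_min_volume || m < 3L)
    return(structure(TRUE, eigenvalues = NULL))
  if (is.null(spectrum)) spectrum <- .graph_spectrum(graph, 2L, params)
  l <- spectrum$values
  single <- l[1] < params$lambda1_max && l[2] > params$lambda2_min
  structure(single, eigenvalues = l)
}

#' Spectral clustering of a structure into nucleus cores
#'
#' Embeds the included voxels in the eigenvectors of the random-walk
#' Laplacian corresponding to the k smallest-absolute eigenvalues and runs
#' k-means for each candidate k in `2..k_max`, restarted `n_restarts` times
#' (the restart with the smallest mean within-cluster point-to-centroid
#' distance is kept). The k with the highest mean silhouette wins. Each core
#' is summarized by its centroid, its centerline orientation
#' ([core_centerline()]) and an ellipsoid approximation of its shape
#' ([core_ellipsoid()]).
#'
#' @param graph An `affinity_graph`.
#' @param structure The `nucleus_structure` the graph was built from
#'   (positions and orientations of the member voxels).
#' @param params A [split_params()].
#' @param spectrum Optional precomputed spectrum.
#' @param seed Optional integer seed making the k-means restarts (and the
#'   silhouette subsample) reproducible.
#' @return List of `nucleus_core` objects (fields `members` - structure
#'   voxel indices -, `centroid`, `centerline`, `ellipsoid`), with the
#'   silhouette-by-k table, the included-voxel labels, and the eigenvalues
#'   attached as attributes `silhouette`, `labels` and `eigenvalues`.
#' @export
cluster_cores <- function(graph, structure, params = split_params(),
                          spectrum = NULL, seed = NULL) {
  stopifnot(inherits(graph, "affinity_graph"))
  if (!is.null(seed)) set.seed(seed)
  m <- length(graph$included)
  if (m < 3L) stop("too few included voxels to cluster")
  if (is.null(spectrum))
    spectrum <- .graph_spectrum(graph, min(params$k_max, m - 1L), params)
  K <- ncol(spectrum$vectors)
  sil_idx <- if (m > params$silhouette_sample)
    sort(sample(m, params$silhouette_sample)) else seq_len(m)

  candidates <- list()
  sil_tab <- data.frame(k = integer(0), silhouette = numeric(0))
  for (k in 2:min(params$k_max, K)) {
    emb <- spectrum$vectors[, seq_len(k), drop = FALSE]
    best <- NULL; best_score <- Inf
    for (r in seq_len(params$n_restarts)) {
      km <- tryCatch(
        suppressWarnings(kmeans(emb, centers = k, iter.max = 50L, nstart = 1L)),
        error = function(e) NULL)
      if (is.null(km)) next
      dist_pc <- sqrt(rowSums((emb - km$centers[km$cluster, , drop = FALSE])^2))
      score <- mean(dist_pc)
      if (score < best_score) { best_score <- score; best <- km }
    }
    if (is.null(best)) next
    sil <- mean_silhouette_cpp(emb[sil_idx, , drop = FALSE],
                               best$cluster[sil_idx], k)
    sil_tab <- rbind(sil_tab, data.frame(k = k, silhouette = sil))
    candidates[[as.character(k)]] <- best$cluster
  }
  if (nrow(sil_tab) == 0L)
    stop("k-means failed for every candidate k (degenerate embedding)")
  k_best <- sil_tab$k[which.max(sil_tab$silhouette)]
  labels <- candidates[[as.character(k_best)]]

  cores <- vector("list", k_best)
  for (j in seq_len(k_best)) {
    members <- graph$included[labels == j]
    pos <- structure$positions[members, , drop = FALSE]
    ori <- structure$orientations[members, , drop = FALSE]
    cores[[j]] <- structure(
      list(id = j, members = members, centroid = colMeans(pos),
           centerline = core_centerline(ori, params$small_core_voxels),
           ellipsoid = core_ellipsoid(pos)),
      class = "nucleus_core")
  }
  attr(cores, "silhouette") <- sil_tab
  attr(cores, "labels") <- labels
  attr(cores, "eigenvalues") <- spectrum$values
  cores
}

#' Centerline orientation of a nucleus core
#'
#' For cores of at most `small_core_voxels` voxels, the sign-aligned mean of
#' the voxel orientations (orientation vectors are axial, so each is flipped
#' to a positive dot product with the first voxel's orientation before
#' averaging), normalized. For larger cores, the unit vector maximizing the
#' summed projected magnitude of the voxel orientations, found by minimizing
#' `sum_i (1 - |e_i . v|)` over the unit sphere (spherical-angle
#' parameterization, initialized at the principal direction of the
#' orientation scatter matrix).
#'
#' @param orientations Matrix (n x 3) of unit orientation vectors.
#' @param small_core_voxels Switch-over size (default 12).
#' @return Unit length-3 vector (sign fixed: largest component positive).
#' @export
core_centerline <- function(orientations, small_core_voxels = 12L) {
  if (is.null(dim(orientations))) orientations <- matrix(orientations, ncol = 3)
  n <- nrow(orientations)
  if (n == 0L) stop("empty core")
  if (n <= small_core_voxels) {
    s <- sign(orientations %*% orientations[1, ])
    s[s == 0] <- 1
    v <- colSums(orientations * as.vector(s))
  } else {
    M <- crossprod(orientations)
    v0 <- eigen(M, symmetric = TRUE)$vectors[, 1]
    par0 <- c(acos(min(max(v0[3], -1), 1)), atan2(v0[2], v0[1]))
    obj <- function(p) {
      v <- c(sin(p[1]) * cos(p[2]), sin(p[1]) * sin(p[2]), cos(p[1]))
      sum(1 - abs(orientations %*% v))
    }
    opt <- optim(par0, obj, method = "Nelder-Mead",
                 control = list(maxit = 500L, reltol = 1e-12))
    p <- opt$par
    v <- c(sin(p[1]) * cos(p[2]), sin(p[1]) * sin(p[2]), cos(p[1]))
  }
  v <- .unit(v)
  pivot <- which.max(abs(v))
  if (v[pivot] < 0) v <- -v
  v
}

#' Ellipsoid approximation of a core's shape
#'
#' Principal axes are the eigenvectors of the covariance matrix of the
#' core's voxel locations; the size along each axis is twice the square root
#' of the corresponding eigenvalue. Degenerate cores (fewer than 4 voxels or
#' rank-deficient covariance) keep zero sizes along the deficient axes; a
#' single voxel yields all-zero sizes.
#'
#' @param positions Matrix (n x 3) of voxel positions (um).
#' @return List with `axes` (3 x 3, orthonormal columns) and `sizes`
#'   (length 3, um, decreasing).
#' @export
core_ellipsoid <- function(positions) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  if (nrow(positions) < 2L)
    return(list(axes = diag(3), sizes = c(0, 0, 0)))
  C <- cov(positions)
  ee <- eigen(C, symmetric = TRUE)
  axes <- ee$vectors
  for (c in 1:3) {
    pivot <- which.max(abs(axes[, c]))
    if (axes[pivot, c] < 0) axes[, c] <- -axes[, c]
  }
  list(axes = axes, sizes = 2 * sqrt(pmax(ee$values, 0)))
}

#' Distance from a voxel to a core's ellipsoid surface
#'
#' The centroid-to-surface distance in the direction of the voxel is
#' approximated as `d_cs = sqrt(x'^2 + y'^2 + z'^2)` where each term is the
#' ellipsoid size along a principal axis times the projection of the unit
#' centroid-to-voxel vector on that axis; the voxel-to-surface distance is
#' `|x - centroid| - d_cs`. Negative values (voxel inside the ellipsoid) are
#' returned as-is and clamped to zero by the assignment step. A voxel at the
#' centroid returns 0. Note this is the prescribed construction, not the
#' exact ray-ellipsoid intersection: for strongly anisotropic ellipsoids it
#' overestimates the surface radius (it is an upper bound).
#'
#' @param x Voxel position (um), or an (n x 3) matrix.
#' @param ellipsoid A [core_ellipsoid()].
#' @param centroid Core centroid (um).
#' @return Numeric vector of signed surface distances (um).
#' @export
surface_distance <- function(x, ellipsoid, centroid) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  U <- sweep(x, 2L, centroid)
  D <- sqrt(rowSums(U^2))
  Q <- U %*% ellipsoid$axes
  num <- sqrt(rowSums(sweep(Q, 2L, ellipsoid$sizes, `*`)^2))
  out <- ifelse(D > 0, D - num / pmax(D, .Machine$double.eps), 0)
  as.numeric(out)
}

#' Assign excluded voxels to nucleus cores
#'
#' Voxels excluded from spectral clustering (degree below `d_min`) are given
#' to the core they most likely belong to:
#' `p_ij = exp(-r_vc^2 / 2 sigma_vc^2) * exp(-d_vs^2 / 2 sigma_vs^2)` with
#' `r_vc` the shortest distance from the voxel to the core centerline and
#' `d_vs` the (zero-clamped) distance from the voxel to the core's ellipsoid
#' surface in the direction of the centroid. Ties go to the lowest core id.
#'
#' @param positions Matrix (n x 3) of excluded-voxel positions (um).
#' @param cores List of `nucleus_core` objects.
#' @param sigma_vc,sigma_vs Assignment SDs in um (defaults 2 and 5).
#' @return Integer vector of core labels.
#' @export
assign_low_degree_voxels <- function(positions, cores, sigma_vc = 2,
                                     sigma_vs = 5) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  if (length(cores) == 0L) stop("need at least one core")
  n <- nrow(positions)
  P <- matrix(0, n, length(cores))
  for (j in seq_along(cores)) {
    co <- cores[[j]]
    d <- sweep(positions, 2L, co$centroid)
    proj <- as.vector(d %*% co$centerline)
    rvc2 <- pmax(rowSums(d^2) - proj^2, 0)
    dvs <- pmax(surface_distance(positions, co$ellipsoid, co$centroid), 0)
    P[, j] <- exp(-rvc2 / (2 * sigma_vc^2)) * exp(-dvs^2 / (2 * sigma_vs^2))
  }
  max.col(P, ties.method = "first")
}

# split result for a structure that stays whole
.single_result <- function(structure, eigenvalues = NULL, oversized = FALSE) {
  ori <- core_centerline(structure$orientations,
                         small_core_voxels = min(12L, nrow(structure$orientations)))
  nuclei <- data.frame(id = 1L, x = structure$centroid[1],
                       y = structure$centroid[2], z = structure$centroid[3],
                       volume = structure$volume,
                       ox = ori[1], oy = ori[2], oz = ori[3],
                       n_voxels = length(structure$voxels))
  structure(list(structure_id = structure$id,
                 n_voxels = length(structure$voxels), is_single = TRUE,
                 k = 1L, labels = rep(1L, length(structure$voxels)),
                 eigenvalues = eigenvalues, silhouette = NULL,
                 nuclei = nuclei, cores = NULL, oversized = oversized),
            class = "split_result")
}

#' Split a nucleus structure into its constituent nuclei
#'
#' Orchestrates the three splitting steps for one extracted structure:
#' builds the voxel-pair affinity graph ([build_affinity()]), decides
#' whether the structure is a single nucleus ([is_single_nucleus()]),
#' otherwise clusters the included voxels into cores ([cluster_cores()])
#' and assigns the excluded voxels to cores
#' ([assign_low_degree_voxels()]). Single structures pass through
#' unchanged; the voxel labels always partition the structure. Structures
#' above `params$max_voxels` are reported as oversized and passed through
#' unsplit rather than silently dropped.
#'
#' @param structure A `nucleus_structure`.
#' @param geom A fitted [vessel_geometry()].
#' @param params A [split_params()].
#' @param seed Optional integer seed (k-means restarts, silhouette sample).
#' @return An object of class `split_result`: `is_single`, `k`, per-voxel
#'   `labels`, smallest-absolute `eigenvalues`, the silhouette-by-k table, a
#'   per-nucleus `nuclei` data frame (centroid, volume, orientation, voxel
#'   count) and the `cores`.
#' @export
split_structure <- function(structure, geom, params = split_params(),
                            seed = NULL) {
  stopifnot(inherits(structure, "nucleus_structure"))
  n <- length(structure$voxels)
  if (n > params$max_voxels) {
    warning(sprintf("structure %d has %d voxels (> max_voxels = %d); passed through unsplit",
                    structure$id, n, params$max_voxels))
    return(.single_result(structure, oversized = TRUE))
  }
  graph <- build_affinity(structure, geom, params)
  m <- length(graph$included)
  if (m * graph$voxel_volume < params$single_min_volume || m < 3L)
    return(.single_result(structure))
  # cheap two-eigenvalue gate first (loose tolerance, refined only when the
  # second eigenvalue lands near the decision thresholds); the full spectrum
  # is only needed when the structure goes on to clustering
  p_loose <- params; p_loose$eigs_tol <- 5e-3
  spectrum2 <- .graph_spectrum(graph, 2L, p_loose)
  if (length(graph$included) > 400L &&
      spectrum2$values[2] > 0.005 && spectrum2$values[2] < 0.06)
    spectrum2 <- .graph_spectrum(graph, 2L, params)
  single <- is_single_nucleus(graph, params, spectrum2)
  if (single) return(.single_result(structure, attr(single, "eigenvalues")))
  spectrum <- .graph_spectrum(graph, min(params$k_max, m - 1L), params)

  cores <- cluster_cores(graph, structure, params, spectrum, seed)
  labels <- integer(n)
  labels[graph$included] <- attr(cores, "labels")
  excluded <- setdiff(seq_len(n), graph$included)
  if (length(excluded) > 0L) {
    labels[excluded] <- assign_low_degree_voxels(
      structure$positions[excluded, , drop = FALSE], cores,
      params$sigma_vc, params$sigma_vs)
  }
  k <- length(cores)
  nuclei <- do.call(rbind, lapply(seq_len(k), function(j) {
    mem <- which(labels == j)
    pos <- structure$positions[mem, , drop = FALSE]
    ctr <- colMeans(pos)
    ori <- core_centerline(structure$orientations[mem, , drop = FALSE],
                           params$small_core_voxels)
    data.frame(id = j, x = ctr[1], y = ctr[2], z = ctr[3],
               volume = length(mem) * structure$voxel_volume,
               ox = ori[1], oy = ori[2], oz = ori[3], n_voxels = length(mem))
  }))
  structure(list(structure_id = structure$id, n_voxels = n,
                 is_single = FALSE, k = k, labels = labels,
                 eigenvalues = spectrum$values,
                 silhouette = attr(cores, "silhouette"), nuclei = nuclei,
                 cores = cores, oversized = FALSE),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("split_result (structure %d, %d voxels): %s, k = %d\n",
              x$structure_id, x$n_voxels,
              if (isTRUE(x$is_single)) "single nucleus" else "multi-nucleus",
              x$k))
  if (!is.null(x$eigenvalues))
    cat("  eigenvalues:", paste(sprintf("%.4f", head(x$eigenvalues, 4)),
                                collapse = ", "), "\n")
  invisible(x)
}
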