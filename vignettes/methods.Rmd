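---
title: "Quantifying nuclei in 3D vessel-wall stacks: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclei in 3D vessel-wall stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science behind its
pipeline: the models and their assumptions, the parameters that matter, what
the synthetic phantom does and does not emulate, and the numerical choices
made where the design was genuinely open.

## The problem

Two-photon stacks of intact arterial walls show vascular smooth muscle cell
(VSMC) nuclei as bright, elongated blobs (2–6× longer than wide), arranged
in concentric layers within the elastin-bounded media and oriented close to
the circumferential–axial plane of the vessel. Plain
segmentation-plus-counting systematically undercounts: nuclei sit close
enough that dim fluorescent material (off-target staining of extra-nuclear
nucleic acids) bridges neighbours, so one connected structure can contain
two or more nuclei. The package's central contribution is a splitting
procedure that detects such structures and separates them, using only the
geometry that makes VSMC nuclei special.

## Vessel geometry

The vessel is modelled as a straight cylinder over the field of view
(~50–200 µm); curvature of the carotid axis is negligible at that scale. The
centerline (anchor `X_ves`, unit direction `V_ves`) minimizes the variance
of the radial distances of elastin voxels above 15% of the maximum possible
intensity. Only the first and third coordinates of anchor and direction are
free: the vessel runs along the image y axis by acquisition convention, the
anchor's y is pinned to half the stack width (otherwise the anchor could
slide along the line), and the direction is parameterized `(v1, 1, v3)` and
renormalized, which also excludes the degenerate flipped solution.
Levenberg–Marquardt least squares on the centred radial distances converges
in a few iterations from the intensity-weighted centroid and `(0, 1, 0)`.

Two numerical notes. First, the fit thins the suprathreshold voxels
deterministically to at most `fit_subsample = 2e5` points; the estimator
uses order 10^5 observations for 4 parameters and the thinning is
index-striped, so it costs nothing statistically and keeps the fit at a
second or two. Second, for *mixtures* of shells at different radii the
objective is nearly flat in the axis angle (between-shell variance
dominates), so voxelization can move the discrete argmin by a fraction of a
degree; the tests check both the angle and the sharper property that the
returned solution's objective value is at least as good as the true axis's.

The media borders are the outermost crossings of 20% of the maximum of a
Gaussian kernel density of elastin-voxel radii (6% threshold, 0.1 µm grid).
The kernel bandwidth deserves a warning: the published parameter table lists
1.2 for this step while the accompanying text says 0.8. The package defaults
to the table value (`media_kde_bandwidth = 1.2`) and exposes the choice. The
20%-of-max rule has an intrinsic outward bias of `0.84 × bandwidth` on a
sharp-edged wall (the crossing of a step convolved with the kernel), i.e.
about 1.0 µm at bandwidth 1.2 but 0.67 µm at 0.8; border-accuracy checks in
the acceptance tests therefore run at 0.8, where sub-micrometre recovery is
attainable. All KDE grids in the package are aligned to exact multiples of
the 0.1 µm step and extended by four bandwidths beyond the data range, so
normalized densities integrate to one on their grid.

## Nucleus enhancement and extraction

A single-scale Frangi-type vesselness filter enhances the nuclei. The
Hessian is computed by separable Gaussian-derivative convolution in
*physical* units (per-axis kernel SD `sigma / voxel_size`, truncated at ±3
SD — a 37 × 37 × 17 voxel kernel for 0.2 × 0.2 × 0.45 µm voxels at
σ = 1.2 µm), with replicate boundary handling; derivative kernels are
mean-corrected so flat regions give exactly zero response. With eigenvalues
ordered |λ₁| ≤ |λ₂| ≤ |λ₃|, the response is
`(1 − exp(−R_A²/2α²)) · exp(−R_B²/2β²) · (1 − exp(−S²/2C²))` for bright
tubular voxels (λ₂, λ₃ < 0) and zero otherwise. The sensitivities
α = β = 0.15 are strict: short blobs, plates and junction necks are strongly
suppressed — deliberately so, since this is what keeps most adjacent nuclei
from merging in the first place. The third constant is printed unitless as
c = 0.15; an absolute Hessian-norm scale would depend on image brightness,
so the package interprets it as a fraction of the maximum second-order
structure norm `S` in the image (`C = c · max S`), which is configurable.
The exact published filter variant is not fully specified; any standard
single-scale 3D formulation satisfying the package's oracle tests (cylinder
beats sphere, orientation within 5° on a rendered tube, rotation
equivariance) is acceptable, and this one does.

Each voxel also receives the eigenvector of the smallest-|λ| eigenvalue —
the local elongation direction — with a deterministic sign convention (first
non-zero component positive; orientations are axial, so the sign carries no
information). Segmentation thresholds the response strictly above 0.1;
structures are 6-connected components, and those below 54 µm³ are discarded.
Note the threshold acts on the *mask* volume, which for thin nuclei is
dilated to roughly the filter scale; a geometric nucleus of ~60 µm³ yields a
mask of ~60–65 µm³ under the default imaging conditions, comfortably above
the cutoff at ordinary depths.

## Nucleus splitting

Step 1 scores every voxel pair of a structure with three likelihoods —
collinearity (`p_rd`, σ_r = 0.8 µm, the width scale of a VSMC nucleus),
transmural separation (`p_td`, σ_td = 0.8 µm, the thickness scale), and
in-plane orientation (`p_ta`). The printed units of σ_r and σ_td (µm³ in the
parameter table) are taken as a typo for µm: both enter Gaussians of
lengths. The product rule means `p_ta` acts as the exclusion mechanism it is
described as: transmurally oriented voxels (typically bridges between
layers) lose affinity to everything and drop below the degree threshold.
The affinity matrix is stored sparsely; pairs with ρ < 10⁻⁶ are dropped,
which perturbs degrees by far less than the decision resolution (d_min = 40
is absolute, as printed, not normalized by structure size).

Step 2 excludes voxels with degree below 40, recomputes degrees on the
included subset (so the rows of `D⁻¹R` sum to one there; voxels isolated by
the restriction join the excluded set), and takes the k = 10
smallest-absolute eigenvalues of the random-walk Laplacian. These are
computed from the similar symmetric form via a Lanczos (Krylov) iteration on
the shifted operator `I + D^{-1/2} R D^{-1/2}` — largest-algebraic mode, so
no sparse factorization is needed — with a dense fallback for small graphs.
A structure is a single nucleus if its included volume is below 1.8 µm³ or
if λ₁ < 0.01 and λ₂ > 0.02. Since λ₁ of a connected graph is exactly zero,
the operative test is λ₂ > 0.02; a λ₂ in the ambiguous band [0.01, 0.02]
proceeds to clustering (the conservative reading: it allows a split).
For multi-nucleus structures, k-means runs in the eigenvector embedding for
each k in 2…10 with 20 restarts, keeping the restart with the smallest mean
within-cluster point-to-centroid distance, and the k with the highest mean
silhouette wins. Silhouette distances are Euclidean in the same embedding
k-means clusters in (the natural choice; the space is not prescribed), and
for large structures the mean silhouette is estimated on a deterministic
subsample of 2 000 embedded voxels — at that size the estimate is accurate
to ~0.01, far below the separation between candidate k values, and it keeps
the stage linear-ish in structure size. k-means restarts draw from R's RNG;
`split_structure(seed = )` makes them reproducible, and the pipeline derives
per-structure seeds from its configuration seed.

Step 3 assigns each excluded voxel to the core with the highest likelihood,
combining distance to the core centerline (σ_vc = 2 µm) and distance to an
ellipsoid approximation of the core surface (σ_vs = 5 µm). Cores of ≤ 12
voxels use the sign-aligned mean orientation as centerline; larger cores
maximize the summed projected magnitude of voxel orientations over the unit
sphere (Nelder–Mead over spherical angles from the principal direction of
the orientation scatter — the |·| in the objective is non-smooth, so a
derivative-free step from a good start is the robust choice). The
centroid-to-surface distance `d_cs = sqrt(x'² + y'² + z'²)` is the
prescribed construction, not the exact ray–ellipsoid intersection: it is
provably an upper bound on the exact surface radius (Cauchy–Schwarz) and can
overestimate it several-fold for strongly anisotropic ellipsoids in oblique
directions. It is implemented as printed; the tests verify the sphere case
exactly, verify the bound property against the closed-form radius on 1 000
random ellipsoids, and log (rather than enforce) the observed discrepancy.
Negative voxel-to-surface distances (voxel inside the ellipsoid) are clamped
to zero — a voxel inside a core's ellipsoid should not be penalized. Ties in
the assignment go to the lowest core id. Rank-deficient cores keep zero
sizes along deficient axes. The 54 µm³ minimum volume is *not* re-applied to
post-split nuclei: re-filtering is never stated and would undo splits of
unequal pairs.

Structures larger than `max_structure_voxels` (default 150 000) are reported
as oversized and passed through unsplit rather than silently dropped — the
affinity stage is quadratic in voxel count and this is the memory guard.

## The phantom generator

`generate_phantom()` renders what the pipeline expects to see: a tilted,
softly-edged cylindrical elastin shell (red), and nuclei (green) placed on
jittered (angle × axial) grids on concentric layer shells at radii
`vessel_radius + (k − ½) · wall_thickness / n_layers`, oriented along the
local circumferential direction rotated in the tangent plane by a
Normal(0, 10°) helix angle. Nuclei are rendered *bent*, following the helix
path on their layer cylinder (computed in unrolled-cylinder coordinates,
exact to second order in wall curvature): real VSMC nuclei follow the wall,
and perfectly straight rods would give the orientation field an unrealistic
long-range coherence. Intensities decay with depth as
`exp(−z / 80 µm)`, and noise is additive Gaussian with a Poisson-like
signal-dependent term (SD `0.02 + 0.05 √I`) — simple, and sufficient to
stress the global thresholds.

Default study conditions: a 256 × 320 × 112 voxel stack (0.2 × 0.2 × 0.45 µm
voxels), vessel radius 15 µm with an 8 µm wall, 5° tilt, two layers of 30
nuclei with semi-axes 6.5 × 1.5 × 1.5 µm (13 µm long, elongation 4.3). The
layer spacing leaves ~1 µm between layer surfaces; no quantitative layer or
nucleus spacing is published, and these values are phantom conventions
chosen so that the splitting stage is genuinely exercised, not established
biology.

A fraction `touch_fraction` of nuclei forms fused pairs, either side by side
within a layer (parallel, en echelon) or radially stacked across adjacent
layers, staggered along the nucleus axis, with the partner placed only where
it has clearance from all other nuclei. Each pair is connected by a dim
strand (radius 1.2 µm, peak intensity 0.8, dimmest midway) between the
facing nucleus ends. This is a deliberate modelling decision, and the most
consequential one in the package: touching in fluorescence data is mediated
by dim off-target material linking neighbouring nuclei, and the exclusion
machinery of the splitting step (orientation-mismatched, transmurally
oriented link voxels losing degree) is exactly what such links trigger.
Geometric alternatives fail structurally, not marginally: full-length
parallel surface contact survives the filter as a rim-connected crescent
pair whose orientation field stays smooth (λ₂ ≈ 0.1–0.4, far above the 0.02
gate), and tip-to-tip collinear contact is indistinguishable *in principle*
from a single long nucleus given only positions and orientations — the
collinearity likelihood is designed to link exactly such configurations.
Those configurations are therefore genuine blind spots of the method, which
the phantom does not hide; they are simply not what the generator's `fused
pair` flag means.

What the phantom does not emulate: optical PSF anisotropy and deconvolution
artefacts, intensity mottle within nuclei (chromatin texture), mRNA speckle
clutter away from nuclei, curved vessel axes, and real biological variation
in nucleus size and shape. Passing tests on phantoms therefore demonstrate
the pipeline's correctness under its stated geometric assumptions, not
performance on any particular microscope's data.

## Validation problem sizes

The test suite validates, among others: the likelihood closed forms to
1e-9; spectral clustering against an independent connected-components oracle
on 100 random block graphs (≤ 200 nodes); centerline recovery within 0.5°
and media borders within 1 µm on noiseless shells, with graceful degradation
(2° / 2 µm) at shell SNR 5 under shot-noise-dominated noise — the 6% media
threshold presumes a detector background below roughly 4% of full scale, as
is typical for two-photon detection, and a *background* SD that large would
flood the global thresholds instead; fused-pair resolution on 24 dedicated pair phantoms
(12 cross-layer, 12 same-layer; ≥ 90% must yield exactly two nuclei, and
≥ 95% of single-nucleus decoys must pass through unsplit); and end-to-end
count recovery on five 60-nucleus vessels with 30% touching nuclei (mean
absolute with-splitting error ≤ 7%, with-splitting strictly better than
without on every seed, and the without-splitting undercount growing with the
touching fraction). These sizes are the package's validation defaults,
chosen to keep the full suite within a practical wall-clock budget; the
generator and thresholds do not change with them.

## Known limitations

- Same-layer nuclei touching in parallel along their full length, and
  collinear tip-to-tip chains, cannot be split by the likelihood model (see
  above); counts degrade gracefully (one merged structure counts as one).
- The single-nucleus gate reduces to λ₂ > 0.02 in practice; structures whose
  link is strong enough to push λ₂ above the gate are kept whole even when
  they contain two nuclei.
- The media-border estimate inherits an outward bias proportional to the KDE
  bandwidth (see the bandwidth discussion); thin walls (< ~3 bandwidths) will
  additionally lower the density plateau.
- The centerline model is a straight cylinder; strongly curved or tapering
  vessels violate it.
- All randomness is seeded, but k-means label *numbering* (not membership)
  may differ across platforms with different BLAS rounding in rare
  tie cases.
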