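# vesselnuclei

Automated quantification of cell nuclei in two-channel 3D fluorescence image
stacks of intact arterial walls.

Vascular smooth muscle cells (VSMCs) are the working cells of the arterial
media. Counting them in intact, unsectioned vessels — imaged by two-photon
laser scanning microscopy under controlled loading — is hard because their
nuclei are elongated (2–6× longer than wide), organized in tight concentric
layers, and frequently so close together that segmentation merges several
nuclei into one connected structure, biasing counts low by tens of percent.
`vesselnuclei` implements a full analysis pipeline for such data, built
around a spectral-clustering *nucleus splitting* procedure that detects and
separates multi-nucleus structures.

The package is aimed at vascular biomechanics and mechanobiology labs
quantifying medial cell content, transmural cell distributions, and medial
cell density from 3D stacks (green = nuclear stain, red = elastin
autofluorescence or stain).

## Method

1. **Vessel geometry.** A straight cylinder is fitted to suprathreshold
   elastin voxels (threshold 15% of the maximum possible intensity) by
   minimizing the variance of radial distances
   `eps = sum_i (r_i - rbar)^2 / (n-1)` over the centerline anchor `X_ves`
   and direction `V_ves`, with
   `r_i = | X_i - (X_ves + V_ves (V_ves . (X_i - X_ves))) |`.
   The media borders are the first and last radii where the Gaussian kernel
   density of elastin voxel radii (6% threshold) exceeds 20% of its maximum.
2. **Nucleus enhancement.** A single-scale 3D Frangi-type vesselness filter
   (Gaussian scale 1.2 µm, sensitivities α = β = c = 0.15) enhances bright
   elongated structures; thresholding the response at 0.1 and 6-connected
   component labeling with a 54 µm³ minimum volume yields nucleus
   structures. The eigenvector of the smallest-absolute Hessian eigenvalue
   gives each voxel the local elongation direction `E_i`.
3. **Nucleus splitting.** For each structure, every voxel pair (i, j) gets a
   likelihood of belonging to the same nucleus:
   `rho_ij = p_rd · p_ta · p_td` with
   - `p_rd = exp(-(r_ij² + r_ji²) / 2σ_r²)` — collinearity of positions and
     orientations (`r_ij` = distance of voxel i to the line through j along
     `E_j`; σ_r = 0.8 µm),
   - `p_td = exp(-d_td² / 2σ_td²)` — transmural separation along the radial
     direction through the structure centroid (σ_td = 0.8 µm),
   - `p_ta = (1 - |V̂_tm·E_i|)(1 - |V̂_tm·E_j|)` — both orientations in the
     circumferential–axial plane.
   Voxels with degree `d_i = Σ_j rho_ij < 40` are excluded; the eigenvalues
   of the random-walk Laplacian `L_rw = I - D⁻¹R` decide whether the
   structure is a single nucleus (λ₁ < 0.01 and λ₂ > 0.02); otherwise
   k-means on the k smallest-eigenvalue eigenvectors (k = 2…10, 20 restarts,
   best mean silhouette) finds the nucleus cores, and excluded voxels join
   the core with the highest likelihood
   `exp(-r_vc²/2σ_vc²)·exp(-d_vs²/2σ_vs²)` (centerline distance and
   ellipsoid-surface distance; σ_vc = 2 µm, σ_vs = 5 µm).
4. **Quantification.** Counts with/without splitting, transmural nucleus
   density distributions (KDE, bandwidth 1 µm, 0.1 µm grid), and medial cell
   density (nuclei between the media borders per media volume).

A synthetic phantom generator (`generate_phantom()`) renders tilted
cylindrical elastin shells with layered, curvature-following elongated
nuclei, optional fused (touching) pairs, depth attenuation and noise — with
full ground truth, so the entire pipeline is validated without microscope
data.

## Worked example

```r
library(vesselnuclei)

# a 60-nucleus synthetic vessel, 30% of nuclei in touching pairs
spec <- phantom_spec(touch_fraction = 0.3, seed = 7)
ph   <- generate_phantom(spec)
an   <- run_pipeline(ph$red, ph$green, vessel_config(seed = 7))
print(an)
#> vessel_analysis
#>   centerline direction (0.063, 0.996, 0.063), media [14.0, 24.3] um
#>   counts: 55 without splitting, 59 with splitting (4 multi-nucleus structures)
#>   medial density 7.41e+05 nuclei/mm^3 (59 nuclei in media)
nrow(ph$truth)
#> [1] 60
```

The phantom truly contains 60 nuclei. Plain connected-component counting
finds 55 structures (touching nuclei merged, −8.3%); the splitting procedure
recognizes 4 multi-nucleus structures and recovers 59 nuclei (−1.7%). The
recovered centerline is within 0.15° of the true (tilted) vessel axis, and
the media borders bracket the true wall. `an$distribution_with` holds the
transmural density grid (`plot(an$distribution_with)` shows the two nucleus
layers as local maxima), and `an$density` the medial cell density.

Individual stages are exported (`fit_centerline()`, `vesselness3d()`,
`extract_structures()`, `split_structure()`, …) and a thin command-line
wrapper ships in `inst/cli/vesselnuclei`
(`vesselnuclei simulate|analyze --help`-style usage in the file header).

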