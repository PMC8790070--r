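Package: vesselnuclei
Title: Nucleus Quantification and Splitting in 3D Vessel-Wall Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated quantification of cell nuclei in two-channel 3D
    fluorescence image stacks of intact arterial walls. Fits a straight
    cylinder to the elastin channel to recover the vessel centerline,
    locates the media borders from the transmural elastin density,
    enhances elongated nuclei with single-scale 3D vesselness filtering,
    extracts connected nucleus structures, and splits structures that
    contain several touching elongated nuclei by spectral clustering of
    voxel-pair likelihoods built from nucleus geometry. Reports nucleus
    counts with and without splitting, transmural cell-density
    distributions and medial cell densities, and ships a synthetic
    vessel phantom generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
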