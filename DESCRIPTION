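Package: nanodyn
Title: Membrane Receptor Nanoclustering, Mobility and Chemotaxis Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis chain for membrane receptor dynamics
    studies: single-particle tracking of TIRF movies (sub-pixel spot
    detection, optimal frame-to-frame linking), short time-lag diffusion
    coefficients (D1-4) with mobile/immobile classification, receptor
    stoichiometry by monomer intensity calibration and photobleaching
    step counting, raster image correlation spectroscopy (RICS) for
    membrane diffusion, chemotaxis track metrics (forward migration
    index, straightness), and the statistical stage of a lipidomics
    workflow (internal-standard normalization, QC filtering,
    Mann-Whitney with Benjamini-Hochberg correction). Includes seeded
    synthetic-data generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    jsonlite,
    minpack.lm,
    mclust,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
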