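Package: structmorph
Title: Segmentation, Morphometric Classification and Dynamics of
    Fluorescent Subcellular Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying the spatial organization of filament-forming
    proteins (septins, Cdc42 effector proteins, actin) in 16-bit fluorescence
    micrographs.  Segments cells and sub-cellular structures by manual-threshold
    rules with local Gaussian background subtraction, characterizes every
    structure with region properties, neighbor-distance statistics and
    rotation-invariant Fourier boundary descriptors, clusters the morphometric
    feature space (PCA + DBSCAN with optional Gaussian-mixture refinement),
    merges fine classes into interpretable groups by co-alignment of their
    area-fraction loadings, and reports per-image class area fractions.
    Companion tools quantify cell migration (track linking, speed,
    directionality ratio, rose histograms), actin stress-fiber shortening,
    focal-adhesion morphometry and pixelwise Pearson colocalization.  A
    synthetic-microscopy generator with full ground truth (dots, fragments,
    filaments, rings, aggregates over a noisy graded background, plus
    persistent-random-walk trajectories) makes every stage testable without
    real data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
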