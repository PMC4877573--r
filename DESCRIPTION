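Package: epidermtex
Title: Texture Descriptors for Plant Identification from Leaf Epidermis
    Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies plant species from grayscale microscopy images of
    dissociated leaf epidermis using texture descriptors: cumulative
    circular (disk) and circular-angular (ring-wedge) partitions of the
    centered Fourier magnitude spectrum, a corrosion-inspired cellular
    automaton whose cumulative eroded mass forms the feature curve, and
    local binary pattern histograms.  Includes percentile-saturation
    contrast stretching, PCA reduction, 1-NN and regularized linear
    discriminant classification under stratified repeated
    cross-validation, split-environment evaluation protocols for
    phenotypic plasticity, fusion of texture features with manual
    stomatal traits (density, guard-cell length, complex width), and a
    seeded synthetic epidermis-texture generator for fully reproducible
    experiments.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    png,
    tiff,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    EBImage,
    class,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
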