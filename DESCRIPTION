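Package: vertrab
Title: Orientation-Resolved Trabecular Morphometry and Micro-Finite-Element
    Analysis of Vertebral Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale pipeline for studying how vertically oriented
    trabecular bone determines whole-vertebra compressive stiffness and
    strength. Generates voxelized vertebral-body phantoms with ground-truth
    compartment and orientation labels, reads and writes 3D volumes
    (MetaImage, NIfTI, TIFF stacks), peels the cortical shell and endplates
    from binary images, segments individual trabeculae and classifies them
    as vertical, oblique or horizontal, computes orientation-resolved bone
    volume fractions including the vertical tissue fraction, solves
    voxel-based linear-elastic micro-finite-element models with and without
    the shell, decomposes highly stressed tissue by compartment and
    orientation, and runs the cohort-level regression comparisons of the
    candidate strength predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    tiff,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
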