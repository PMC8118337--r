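Package: erythroshape
Title: 3D Red Blood Cell Shape Phenotyping from Confocal Z-Stacks
Version: 0.1.0
Authors@R:
    person("erythroshape", "developers", email = "erythroshape@example.org",
           role = c("aut", "cre"))
Description: End-to-end phenotyping of single red blood cells imaged as 3D
    confocal z-stacks. Raw anisotropic stacks are cropped per cell,
    interpolated to isotropic voxels, binarized and converted to closed
    triangle meshes; each mesh is summarized by a 544-dimensional rotation-
    and translation-invariant spherical-harmonics descriptor; a dual-stage
    neural network first assigns one of seven morphological classes (with an
    unknown-confidence threshold) and then places stomatocyte-discocyte-
    echinocyte (SDE) shapes on a continuous score from -1 (spherocyte) to +1
    (echinocyte III). A parametric shape simulator generates canonical RBC
    meshes, continuous morphs and synthetic confocal-like stacks so that the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
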