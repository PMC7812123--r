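Package: endocastr
Title: Quantitative Comparison of Brain and Endocast Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitatively comparing the outer brain surface of an
    individual with the endocranial cast (endocast) of the same individual.
    Provides paired synthetic phantoms with known ground truth, normalized
    mutual information rigid volume registration, deformable-sphere
    (shrink-wrap) surface extraction from volumetric images, curvature-based
    ridge/ravine detection of sulcal imprints on triangle meshes, kernel
    diffeomorphic surface registration with labelled-curve transport, and
    curve-matching statistics with extrapolated distance maps and surface
    displacement maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
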