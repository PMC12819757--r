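Package: cartistrain
Title: Full-Volume Strain Analysis of Patellar Cartilage from Displacement-Encoded MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for displacement-encoded MRI of articular
    cartilage under indentation, before and after osteochondral allograft
    (OCA) transplantation. Converts complex-valued phase-encoded volumes to
    displacement fields via quality-guided 3D phase unwrapping, computes
    Green-Lagrange strain tensor fields on tetrahedral meshes (with an
    independent grid-differencing oracle), extracts principal-strain
    outcomes (minimum principal strain and maximum shear strain), builds
    top-view percentile strain maps, and quantifies donor-recipient
    step-off geometry and matched strain changes around the graft rim.
    Includes a synthetic indentation phantom with analytically known
    displacement and strain for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    stats,
    tools,
    utils,
    tibble,
    dplyr,
    ggplot2,
    yaml,
    jsonlite,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
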