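Package: dronecover
Title: Drone Versus Ground-Based Estimation of Habitat Degradation from RGB Imagery
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for assessing goose-induced habitat
    degradation in coastal salt marsh from drone RGB ortho-mosaics. Generates
    seeded synthetic landscapes with known barren / non-shrub / shrub cover,
    classifies imagery by unsupervised k-means clustering with reclassification
    into three land-cover categories, removes salt-and-pepper noise (majority
    filter, boundary clean, minimum-mapping-unit sieve), estimates per-cell cover
    by full pixel enumeration and by virtual step-point transects, assesses
    thematic accuracy (stratified points, confusion matrices, overall accuracy,
    Cohen's kappa), and compares methods with beta generalized linear mixed
    models on Smithson-Verkuilen transformed proportions fitted by adaptive
    Gauss-Hermite quadrature.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    jsonlite,
    tiff,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    readxl,
    optparse
Config/testthat/edition: 3
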