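Package: spisim
Title: Virtual Single-Particle X-Ray Imaging Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale laboratory for x-ray free-electron laser
    single-particle imaging (SPI). Simulates photon-sparse coherent
    diffraction snapshots of an atomic model on an Ewald-sphere detector
    geometry, applies a parametric integrating-detector (AGIPD-style)
    noise model with Gaussian photon peaks and threshold photonization,
    recovers the 3D reciprocal-space intensity from snapshots of unknown
    orientation with the expand-maximize-compress (EMC) algorithm,
    retrieves real-space electron density with ensemble hybrid
    input-output (HIO) phasing, and estimates achievable resolution from
    the 3D R factor at the R = 0.2 threshold. Includes generators for
    synthetic atomic phantoms, calibration histograms and complete
    snapshot datasets, and a study driver that maps resolution against
    snapshot count and detector noise configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    mclust,
    bio3d,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
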