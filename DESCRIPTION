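Package: enmdyn
Title: Elastic Network Models, Coarse-Grained Langevin Dynamics and
    Essential Dynamics for Calpha Protein Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Coarse-grained analysis of collective protein dynamics at
    one-bead-per-residue resolution. Builds elastic networks from Calpha
    coordinates, computes anisotropic-network-model (ANM) normal modes,
    runs Langevin (BAOAB) dynamics on the harmonic network potential,
    performs essential dynamics (trajectory PCA) with PC-space cluster
    selection, and compares methods through dynamic cross-correlation
    maps, thermal B-factor profiles and normalized mode-overlap values.
    Includes a seeded generator of synthetic two-domain structures and
    thermal ensembles with known covariance for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    bio3d,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
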