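Package: mitoconstrict
Title: Mechanics of Mitochondrial Constriction by Localized Membrane Pressure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates constriction of a mitochondrial outer-membrane tubule
    under an inward pressure applied on a narrow axial strip, the geometry of
    an endoplasmic-reticulum contact site. Equilibrium shapes of the
    axisymmetric tube are found by minimizing the Helfrich bending energy at
    zero lateral tension with clamped cylindrical ends, pressure-radius
    curves are traced by warm-started continuation, and the pressures needed
    to reach prescribed neck radii are converted into numbers of polymerizing
    actin filaments and actomyosin contractile-ring tensions. Includes a
    scenario generator (baseline, randomized, rescaled dimensionless twins,
    perturbed initial profiles) and a deterministic reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
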