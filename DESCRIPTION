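Package: coromicro
Title: Microstructure-Based Passive and Active Mechanics of Coronary Arteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Three-dimensional microstructural constitutive modelling of the
    coronary artery wall. Passive stresses arise from elastin and collagen
    fibers with measured orientation mixtures and beta-distributed collagen
    straightening (recruitment) strains; active stresses follow an asymmetric
    triaxial smooth-muscle-cell contraction law integrated over the cell
    orientation family. The loaded vessel is a residually stressed,
    incompressible thick-walled tube: the package maps the opened-up
    zero-stress sector to the pressurised configuration, integrates radial
    equilibrium for luminal pressure, axial force and transmural stress
    profiles, simulates distension-extension protocols, generates synthetic
    biaxial test data, and estimates passive and active material parameters
    jointly by seeded global optimisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    lhs,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
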