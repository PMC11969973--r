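Package: fogsim
Title: Neuromusculoskeletal Gait Simulation and Freezing-of-Gait Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-dynamics simulation of planar bipedal gait with a
    seven-link, eighteen-muscle body driven by a brainstem (midbrain
    locomotor region: pedunculopontine and cuneiform nuclei) and spinal
    central-pattern-generator neural controller. Includes Hill-type
    muscles, spring-damper ground contact, fixed-step Runge-Kutta
    integration, genetic-algorithm optimization of the free controller
    parameters, a two-parameter brainstem-drive sweep, a spectral
    freezing-of-gait detector (freeze ratio plus bilateral correlation),
    and Ward-linkage cluster analysis of freezing episodes with
    nonparametric group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    car
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
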