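Package: placosheet
Title: Elastic Self-Propelled Particle Sheets and Collective-Order Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates two-dimensional elastic sheets of self-propelled
    particles on a fixed Voronoi-neighbor topology, a minimal model of
    ciliated-tissue locomotion in placozoans, and provides the measurement
    stack used to characterise collective motion in tissue flow fields:
    polarization, rotation and dilatation order parameters, a unified
    order measure, similarity (Procrustes) decomposition of frame-to-frame
    motion into affine flow plus velocity fluctuations, a fluctuation-power
    noise proxy, spatial correlation profiles with correlation length and
    integrated susceptibility, finite-size susceptibility of the order
    parameter, and parameter sweeps that locate the order-disorder
    transition. Includes a synthetic vector-field generator with
    controllable affine and noise components, filtering rules for
    empirical optical-flow fields, plain-text file formats, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
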