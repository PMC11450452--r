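Package: bcpnn
Title: Sparsely Spiking Bayesian Confidence Propagation Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulator for modular (hypercolumn/minicolumn) spiking neural
    networks with Bayesian-Hebbian (BCPNN) trace plasticity and
    activity-dependent structural rewiring. Units are Poisson-like spike
    generators driven by a soft winner-take-all membrane model; feedforward
    projections learn sparse distributed representations while recurrent
    projections form attractor associative memories, and feedback
    projections reconstruct inputs. Includes generators for
    prototype-structured synthetic image data and the pattern-completion,
    perceptual-rivalry and distortion-resistance benchmark corruptions, an
    IDX image file reader, and evaluation tools (Gaussian-kernel rate
    estimation, cosine similarity and orthogonality ratio, prototype
    extraction, linear readout).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
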