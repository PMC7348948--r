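Package: rogersfr
Title: Functional Response Analysis with Prey Depletion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of predator and parasitoid functional-response
    experiments in which prey are not replaced during the exposure period.
    Implements response-type selection by polynomial logistic regression,
    maximum-likelihood fitting of the Rogers random-predator equation via
    its Lambert-W closed form, non-parametric bootstrap confidence bands
    with pointwise curve-overlap comparison between treatments, and a
    binomial generalized linear mixed model with an observation-level
    random intercept fitted by adaptive Gauss-Hermite quadrature. A
    synthetic-experiment generator reproduces the cage-assay design of a
    ladybird/parasitoid versus aphid study (7 prey densities x 10
    replicates, aggregate and uniform prey distributions) so that every
    stage of the pipeline can be exercised and validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    lme4,
    pracma,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
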