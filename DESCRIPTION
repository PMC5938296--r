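Package: vgrkit
Title: Visual Grading Regression for Pairwise Image-Quality Observer Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of ordinal pairwise image-quality gradings from visual
    grading studies, as used in CT protocol optimisation. Implements the
    visual grading regression (VGR) model: a cumulative-logit
    (proportional-odds) regression of relative 5-point scores on differences
    in log tube load and reconstruction algorithm, with optional crossed
    patient and observer random intercepts fitted by Laplace approximation.
    Converts fitted coefficients into potential dose-reduction estimates via
    DR = 1 - exp(-b/a) with delta-method, Fieller and parametric-bootstrap
    confidence intervals, quantifies inter- and intra-observer reliability
    with the weighted kappa statistic, and simulates complete grading studies
    from the latent-variable formulation of the model so that every stage of
    the pipeline can be validated without access to reader data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
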