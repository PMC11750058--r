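Package: panelcausal
Title: Panel Regression Designs for Causal Inference Under Unobserved
    Confounding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical designs for estimating causal effects from
    clustered and longitudinal ecological data when unmeasured
    confounders drive both the exposure and the outcome. Implements the
    naive pooled regression, random-intercept mixed models fitted by
    restricted maximum likelihood, econometric fixed effects (within
    transformation and dummy coding), correlated-random-effects designs
    (group mean covariate and group mean centering), first- and
    second-difference designs, and two-way spatiotemporal designs with
    plot and site-by-year terms. Ships a configurable generator of
    confounded site-by-year panels (an oceanography-driven
    snail-abundance system) and a Monte-Carlo study engine that compares
    bias, sampling spread and interval coverage across designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    parallel,
    stats,
    utils
Suggests:
    lme4,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
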