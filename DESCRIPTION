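Package: changepanel
Title: Causal Comparison of Change-Analysis Estimators for Panel Biomarker Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying what change-score, concurrent change-change
    (first-difference fixed-effects), lagged change-change and cross-sectional
    regressions actually estimate when applied to short balanced panels of a
    continuous intermediate disease marker. Provides synthetic panel
    data-generating processes with controllable unobserved time-invariant
    confounding and with violations of the strict-exogeneity and common-trend
    assumptions, the four analysis estimators, a Monte Carlo engine that
    measures their bias over parameter grids, closed-form probability limits
    for every estimator-by-process combination, and a linear structural
    equation model engine (implied moments, path tracing, backdoor path
    enumeration with d-separation) that verifies the theoretical estimands on
    a three-wave panel DAG.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
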