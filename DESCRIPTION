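Package: resilpp
Title: Composite Resilience Indices by Projection Pursuit with an
    Accelerating Genetic Algorithm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building composite regional resilience indices from
    small region-by-indicator panels.  Indicator weighting and region scoring
    use a projection-pursuit model whose projection index (spread times local
    density) is maximized by a real-coded accelerating genetic algorithm.
    Includes min-max standardization with positive/negative indicator
    orientation, regression-based multiple imputation with noise draws,
    exact Jenks natural-breaks classification, an entropy-TOPSIS comparator,
    inverse-distance spatial weights, global and local Moran's I with
    normality/randomization inference and permutation tests, and a synthetic
    panel generator with spatially autocorrelated latent structure for
    fully reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse,
    withr
Config/testthat/edition: 3
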