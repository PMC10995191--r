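Package: agbref
Title: Reference Aboveground-Biomass Maps from Forest Inventories and LiDAR Canopy Height Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-level Monte Carlo pipeline for building reference aboveground-biomass
    (AGB) maps with per-pixel uncertainty from co-located forest inventory plots and
    1-m LiDAR canopy height models. Provides tree-to-plot AGB error propagation
    (height-diameter allometry, wood density, pantropical allometric model), canopy
    height metrics, mixed-effects predictor screening, site and regional log-log
    mapping models, plot-to-landscape uncertainty propagation via model ensembles,
    buffered spatial leave-one-out cross-validation, extrapolation-domain accounting,
    and binned pairwise-covariance metadata for subregion uncertainty estimation.
    Includes a synthetic multi-site forest and CHM generator with known generative
    parameters for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    lme4,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
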