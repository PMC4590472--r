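Package: bactoSeries
Title: Seasonal and Decadal Analysis of Flow-Cytometric Bacterioplankton
    Time Series
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for decadal monthly time series of coastal
    bacterioplankton standing stocks. Derives abundance, mean cell size and
    biomass of low (LNA) and high nucleic acid (HNA) content bacteria from
    flow-cytometry event tables; computes mixed-layer depth, stratification
    index and upper-mixed-layer averages from CTD casts; fits an additive
    decomposition (climatological mean, linear trend, harmonic seasonal
    components selected by the exact Fisher G-test, and a single-lag
    autocorrelation term) with a percent-variance ledger; correlates
    pre-whitened residuals across variables; and analyses temperature-size
    incubation experiments and seasonal-window decadal trends. A synthetic
    data module generates every input with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'bactoSeries-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'synthetic.R'
    'hydrography.R'
    'cytometry.R'
    'decomposition.R'
    'residuals.R'
    'experiments.R'
    'io.R'
    'pipeline.R'
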