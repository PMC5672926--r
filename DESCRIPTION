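Package: lifelost
Title: Loss in Expectation of Life from Flexible Parametric Relative Survival Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Fits flexible parametric relative survival models (restricted
    cubic splines on the log cumulative excess hazard scale) to cancer
    registry data prepared by period analysis with delayed entry, and
    combines the extrapolated relative survival with population life-table
    expected survival to estimate life expectancy, loss in expectation of
    life (LEL), proportion of life lost (PLL) and total life-years lost by
    deprivation group.  Includes exact piecewise-exponential life-table
    arithmetic, internal and external age standardisation, a synthetic
    registry generator with closed-form ground truth, and a config-driven
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    survival,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
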