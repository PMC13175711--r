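Package: reefsync
Title: Synchrony and Portfolio Effects in Benthic Percent-Cover Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying population synchrony and portfolio effects
    in benthic community monitoring data. Implements the community synchrony
    index (the ratio of total-community temporal variance to the squared sum
    of population standard deviations), variance-preserving permutation null
    distributions with quantile-range classification of covariation,
    bootstrap repeated-measures ANOVA for balanced site-by-year designs,
    exact two-tailed binomial tests of cross-site covariance-sign
    consistency, and a synthetic coral-community generator with multinomial
    point-intercept observation noise for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
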