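Package: bruvshealth
Title: Hierarchical Bayesian Health Assessment and Monitoring Power for
    Baited-Video Fish Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing baited remote underwater video station
    (BRUVS) fish-abundance monitoring data against a traffic-light health
    category system. Fits a hierarchical negative-binomial abundance model
    with crossed station, site, year and site-by-year random deviations by
    MCMC (JAGS), computes split R-hat convergence diagnostics, highest
    density intervals, posterior predictive checks and a Bayesian R-squared,
    converts posterior draws into baseline-relative fold-change
    distributions with per-category credibilities (area-under-the-curve
    shares), and evaluates monitoring-design power to detect abundance
    declines by simulation over a grid of decline magnitudes and sampling
    efforts. Includes a synthetic-data generator for the full generative
    process so every stage can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    rjags,
    coda,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
SystemRequirements: JAGS (>= 4.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
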