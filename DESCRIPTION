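Package: kidneyalloc
Title: Cost-Utility Modelling of Deceased-Donor Kidney Allocation Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-state Markov cohort model of deceased-donor kidney
    allocation policy, comparing longevity-matching allocation options against
    current practice for a waitlisted end-stage kidney disease cohort. Provides
    Weibull proportional-hazards transition probabilities with tunnel-state
    expansion for time-since-transplant effects, discounted cost and
    quality-adjusted life-year accumulation, incremental cost-effectiveness
    ratios and net monetary benefit, probabilistic sensitivity analysis by
    Monte-Carlo parameter sampling, and a synthetic linked-registry generator
    so that model fitting and allocation-rule subsetting can be exercised
    without access to restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    flexsurv,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
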