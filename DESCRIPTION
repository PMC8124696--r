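Package: pm25decide
Title: Risk and Decision Analysis for Future PM2.5 Concentration Increase
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A risk-and-decision analysis pipeline for urban air quality
    planning under uncertainty. Risk factors (population growth, economic
    growth, temperature increase) are described by cumulative probability
    curves of their annual increase rates, discretized into High/Medium/Low
    levels, and propagated through an event tree to a distribution over
    PM2.5 concentration-increase consequences with Bayes-inverted
    conditional risk ratings. Mitigation sectors are valued per scenario by
    benefit-per-ton monetization, compared by expected monetary value (EMV)
    and exponential expected utility, and ranked by a weighted-sum
    multi-criteria decision analysis with discrete and continuous
    weight-simplex sensitivity surfaces. Ships the Los Angeles-Long Beach
    Metro Area case study as a packaged configuration together with a
    generator of random, structurally valid cases for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
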