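Package: elfarolcare
Title: El Farol Bar Games and Belief Dynamics for Healthcare Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying healthcare-seeking behaviour as a congestion
    game. Implements a generalized El Farol bar game (payoffs, Poisson-binomial
    attendance beliefs, fictitious play, pure Nash equilibrium enumeration), an
    exponential belief-update model of daily hospital-visit experience driven
    by outpatient count time series, a composite healthcare payoff index built
    from ratio-standardised service indicators, and a seeded synthetic
    generator for daily visit series with weekday and monthly structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
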