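Package: divwave
Title: Collapse-Driven Population Dynamics and Diversity Waves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates communities of species sharing a single saturated
    carrying capacity whose dynamics are driven by episodic whole-population
    collapses followed by instantaneous redistribution of the freed-up
    resources. Implements the basic fixed-richness model and seven published
    variants (neutral drift, exponential fluctuations, interconnected
    environments, Kill-the-Winner, Kill-the-Loser, heterogeneous fitness,
    and resilience), together with streaming observables: diversity traces,
    wave segmentation, time-aggregated and snapshot species abundance
    distributions, power-law tail-exponent estimation, jump/memory series,
    and fitness heatmaps. A fast compiled stepper is validated against a
    pure-R reference implementation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
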