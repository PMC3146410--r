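Package: accessineq
Title: Standardized Inequality in Geographic Accessibility to Health Facilities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures inequality in geographic accessibility to health
    facilities from road-network travel times. Computes shortest-path
    travel time from population-weighted demand blocks to the nearest
    facility under a road-class speed model, summarizes the travel-time
    distribution with the relative mean difference D (twice the Gini
    coefficient), and standardizes D by its Monte Carlo expectation under
    complete spatial randomness (CSR) relocation of within-region
    facilities, giving the ratio R = D / Dbar used to rank regions for
    health-resource priority setting. Includes a synthetic scenario
    generator (grid road networks, skewed block populations, regular,
    clustered, circular and random facility layouts) so the whole pipeline
    is testable without external geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
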