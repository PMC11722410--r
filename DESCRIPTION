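Package: mlscoop
Title: Multilevel Selection Dynamics of Cooperators and Cheaters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stochastic simulator and analytical toolkit for two-level
    (individual and group) selection dynamics in group-structured
    populations of social (cooperator) and asocial (cheater) individuals.
    Groups grow by within-group reproduction on a fixed number of sites,
    reproduce by splitting with random allocation once a size threshold is
    reached, and die under neutral, relative or absolute group-fitness
    regimes. Companion analytics provide splitting-threshold absorption
    probabilities, proliferation and competition thresholds in the
    high-survival limit, and fixation probabilities in the rare-group-death
    (Moran) limit. An off-lattice agent-based biofilm model with
    matrix-producing and non-producing cells serves as a concrete
    realization of the same dynamics. Core simulation loops are implemented
    in C++ via Rcpp.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
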