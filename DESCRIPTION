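Package: guardmate
Title: Population Dynamics of Competing Male Mating Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A 17-compartment ordinary-differential-equation model of two
    competing male mating strategies, multiple mating and mate guarding, in a
    population with a distinct post-fertile female life stage. Provides the
    rate laws (density-dependent mortality, paternity theft, fertility loss),
    numerical integration to equilibrium with dominance classification, adult
    and operational sex ratios, two-dimensional parameter sweeps with phase
    diagrams, dominance-boundary extraction with interpolated sex-ratio
    values, and a command-line interface for simulation and plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
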