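Package: serialcoex
Title: Serial-Dilution Competition and Coexistence of Microbial Strains on a
    Single Resource
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact simulation and analytic theory for microbial strains
    competing for a single finite resource under serial dilution. Each strain
    is described by a lag time, an exponential growth time (reciprocal growth
    rate), and a yield (cells per unit resource). The package solves the
    per-round saturation-time equation exactly, decomposes pairwise selection
    coefficients into lag, growth, and higher-order coupling components,
    iterates the round-to-round recurrence and its continuous-round ODE
    approximation, and provides community-level analyses: lag-growth tradeoff
    fitting, the resource-density coexistence window, fixed-point spaces of
    neutrally coexisting communities, keystone-strain identification, invasion
    analysis, pairwise tournaments, and detection of non-transitive
    (rock-paper-scissors) competition. A synthetic ensemble generator and a
    randomized scenario search construct communities exhibiting each
    phenomenon.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
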