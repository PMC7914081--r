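Package: oralca
Title: Cellular-Automaton Simulation of Oral Microbial Community Succession
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic cellular-automaton model of oral microbial community
    succession on a periodic lattice, in which decomposition-product (public
    good) negative feedback is encoded as neighbour-dependent lag-phase
    induction for two behavioural roles (collaborators and scammers).
    Includes a delay-logistic integrator (method of steps, fixed-step RK4),
    dynamic-response classification and least-squares identification of
    reproductive and reaction delays with bootstrap intervals, Monte-Carlo
    community sampling from published parameter intervals, Simpson alpha
    diversity and population time-series summaries, spatial-aggregation
    permutation tests, and hierarchical clustering of climax communities with
    cophenetic-correlation model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml,
    jsonlite,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
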