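Package: quorumsim
Title: Agent-Based Evolution of Quorum-Sensing-Controlled Cooperation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based evolutionary simulation of bacterial quorum sensing
    in group-structured populations. Three regulatory traits -- basal signal
    production rate, signal response threshold, and positive-feedback
    auto-regulation -- co-evolve under variable population density and
    controlled genetic mixing. The package provides closed-form signal
    equilibria (with an ODE oracle), a density-grid payoff model with
    threshold-dependent public-good benefits, a Wright-Fisher-like
    generational loop with mutation and constitutive-cheat injection, and
    the statistical readouts used to interrogate evolved strategies:
    cooperation-onset curves, the signal/response coordination-line
    regression, individual-group assortment analysis with ANCOVA slope
    comparison, a two-level Price decomposition of selection, and a
    mass-transfer (diffusion-sensing) assay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stats,
    generics,
    ggplot2,
    deSolve,
    yaml,
    jsonlite,
    readr,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
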