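Package: modnet
Title: Evolution of Modularity in Connectively Evolving Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for studying whether computational efficiency
    alone can drive the evolution of modularity in feed-forward neural
    networks. Provides a clonal genetic algorithm over three-layer networks
    whose input-to-hidden connections (presence/absence and weight) both
    evolve, a set of named scenario presets covering gradualistic weight and
    connective mutation regimes, a duplication-based growth regime in which
    whole modules are copied together with their evolved weights, and
    modularity quantification of evolved connection masks via Newman's Q,
    a clique-based faction criterion optimised by Tabu search, Girvan-Newman
    community detection, and degree-preserving null models. Results are
    returned as tibbles with broom-style tidiers and ggplot2 plotting
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
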