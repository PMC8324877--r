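Package: teplex
Title: State-Resolved Transfer Entropy Rules and Multiplex Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates state-resolved causal interactions between brain
    regions from resting-state fMRI ROI time series.  Continuous BOLD
    signals are z-scored and ternarized into activation (1), deactivation
    (-1) and null-activation (0) events; for every ordered region pair the
    local (per state-triple) transfer entropy of each of the 27 possible
    interaction rules is estimated with plug-in frequencies and screened
    against a time-reshuffling null.  The selected rules are classified
    into four functional interaction classes (ActS, ActO, TfS, TfO) that
    form the layers of a three-level directed weighted multiplex network,
    which is characterized by weighted reciprocity and multireciprocity,
    a Cycle/Flux triad-motif census scored by intensity and coherence,
    strength-based centrality classes, and directed weighted modularity,
    each with randomization-based significance.  A synthetic-data module
    generates ternary dynamics with planted rule couplings, continuous
    signal wrappers and random multiplex networks so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
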