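Package: burstnet
Title: Temporal Networks with Prescribed Inter-Event Time Distributions
Version: 1.0.0
Authors@R:
    person("burstnet", "developers", email = "burstnet@example.org",
           role = c("aut", "cre"))
Description: Spanning-tree construction of discrete-time temporal networks in
    which every node and link switches between active and inactive states so
    that their inter-event time (IET) distributions match prescribed targets,
    either bursty discrete power laws or Poisson-like discrete exponentials.
    Supports static, growing (temporal Barabasi-Albert) and rewiring
    underlying topologies, exact and analytic consistency checking of target
    distribution triples, extraction of inter-event and inter-communication
    times, discrete maximum-likelihood fitting, burstiness and memory
    summaries, aggregated weighted networks with node-strength normalization,
    SocioPatterns-style contact file input/output, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
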