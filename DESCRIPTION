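Package: spitenet
Title: Co-Evolution of Spiteful Behavior and Dynamic Interaction Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Agent-based simulation of the Prisoner's Delight game on a
    weighted, directed, dynamic interaction network in which agents
    simultaneously learn whom to visit (Roth-Erev reinforcement with
    discounting and choice error) and how to behave (payoff-biased imitation,
    with total-payoff and Moran-process variants). Tracks per-agent and
    aggregate measures of correlated interaction, ordered visitor-host
    coupling shares, per-strategy payoffs and fixation. Also provides the
    exact best-response analytic model of spite invasion (invasion thresholds,
    expected visitor counts, aggregate correlation at invasion) and the
    classic mean-field anti-correlation benchmark r > c/b.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
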