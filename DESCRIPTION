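Package: discoursenet
Title: Discourse Network Analysis of Policy Debates
Version: 0.1.0
Authors@R:
    person("Policy Networks Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for discourse network analysis of coded media statements in
    contested policy debates. Reads tables of actor statements (who said what
    about which argument, agreeing or disagreeing), aggregates them into
    actor-by-concept stance matrices, projects these into weighted actor
    networks via congruence, conflict and subtract transformations with
    average-activity normalization and thresholding, detects discourse
    coalitions by Girvan-Newman edge-betweenness clustering with
    modularity-based partition selection, and tabulates per-concept
    agreement/disagreement frequencies over time windows. Includes a seeded
    synthetic statement-corpus generator with planted coalition structure for
    end-to-end validation, plus GraphML/GEXF/CSV exporters and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    igraph,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
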