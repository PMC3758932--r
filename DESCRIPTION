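Package: pcrnet
Title: Perceived Causal Relations Scaling and Symptom Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing Perceived Causal Relations (PCR) scaling data:
    per-participant symptom-frequency ratings (0-7) and directed pairwise causal
    ratings (0-10) with typed missingness (by design vs by intention). Implements
    mean causal/effect association scoring with paired cause-vs-effect contrasts
    and Holm-Bonferroni control, percentile-bootstrap moderation, mediation and
    moderated-mediation models, directed weighted symptom networks with
    outdegree, indegree and inverse-weight betweenness centrality evaluated
    against permutation nulls, and per-participant enumeration of bounded-length
    causal feedback loops with their association to symptom burden. Includes a
    seeded synthetic-population generator with a known ground-truth causal
    weight matrix so every stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
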