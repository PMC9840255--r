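Package: retroassess
Title: Assessing Synthetic-Accessibility Scores Against Retrosynthesis
    Tree Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A testbed for evaluating synthetic-accessibility (SA) scores
    against the outcomes and internals of template-based retrosynthesis
    planning. Implements a Monte Carlo tree search (MCTS) planner with
    upper-confidence-bound leaf selection and a depth-penalised reward
    that can be partially replaced by an SA score, a closed toy string
    chemistry with an exact brute-force synthesizability oracle, search
    tree node classification into solved / not-solved / internal nodes,
    tree complexity statistics, and an assessment suite (ROC curves with
    Youden-optimal thresholds, rank correlations with tree complexity,
    one-sided paired t-tests on node pairs, node-level discrimination
    AUCs, and route-finding precision and sensitivity).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
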