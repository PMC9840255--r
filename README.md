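# retroassess

Tools for asking whether synthetic-accessibility (SA) scores — fast
per-molecule estimates of how easily a structure can be synthesized — can
predict and improve template-based retrosynthesis planning. The package is
aimed at cheminformatics researchers who develop or evaluate SA scores and
want a controlled, fully reproducible testbed for the question before
committing to expensive runs on real compound sets.

## What it implements

* **An MCTS retrosynthesis planner.** Nodes are partial solutions
  (multisets of molecules with per-molecule transform counts); leaf
  selection maximises the upper confidence bound

  $$UCB = \frac{Q}{N_p} + 1.4\sqrt{\frac{2 \ln N_{parent}}{N_p}},$$

  and the reward backpropagated from a terminal node of depth $m$ with
  $M_s$ of $M$ molecules in stock is

  $$r = c\,\mathcal{SA} + (0.95 - c)\,\frac{M_s}{M} + \frac{0.05}{1 + e^{m - 4}},$$

  where $c \in \{0, \tfrac14, \tfrac24, \tfrac34\} \times 0.95$ replaces a
  fraction of the reward by a unit-scaled SA score ($c = 0$ is the native
  planner).
* **A closed toy chemistry** (`generate_world()`): molecules are strings,
  templates strictly simplifying rewrites, so an exact brute-force oracle
  (`oracle_min_depth()`) supplies ground-truth minimal synthesis depth —
  including genuinely unsynthesizable targets — plus an ideal
  `oracle_score()` and a `noise_score()` negative control.
* **Search-tree analysis**: node classification into solved / not solved
  (no path to a solved leaf) / internal, tree complexity statistics (node
  count, maximum level width, not-solved leaves), and extraction of
  (internal, not-solved) sibling and parent–child node pairs.
* **The statistical assessment**: ROC curves with Youden-optimal
  thresholds and accuracy, dual-route AUC (trapezoid and pairwise
  probability, kept as mutual oracles), Spearman correlations of scores
  with tree complexity, one-sided paired t-tests on node pairs, pooled
  node-level discrimination AUC tables, and route-finding
  precision/sensitivity.
* **An end-to-end driver** (`run_experiment()`) covering plan → classify →
  score → assess, including the reward-replacement sweep over $c$, with
  JSON/CSV export, and a thin CLI (`inst/cli/retroassess.R`) with
  `genworld` / `plan` / `classify` / `run` verbs.

## Worked example

```r
library(retroassess)

world <- generate_world(alphabet_size = 4, n_templates = 20,
                        stock_size = 30, stock_max_len = 3, seed = 1)
world
#> toy_world: alphabet 4, 20 templates, 30 stock molecules (seed 1)

oracle_min_depth(world, "abca")$min_depth   # exact ground truth
#> [1] 2

tree <- mcts_search("abca", world, planner_config(iteration_limit = 100))
tree
#> search_tree: 5 nodes, root 'abca', route found (2 solved leaves)

labels <- classify_nodes(tree)
table(labels)
#>   internal not_solved     solved
#>          2          1          2

tree_stats(tree, labels)
#> tree_stats: 5 nodes, width 2, depth 2, 2 solved / 1 not-solved leaves
```

The target `abca` needs at least two reaction steps; the search finds a
route, and the tree contains one dead branch (the `not_solved` node) that
a good SA score should have ranked below its `internal` sibling — exactly
what the pair tests and discrimination AUCs quantify at scale:

```r
roc_curve(c(0.9, 0.8), c(0.7, 0.85))
#> roc_result: AUC 0.750, best threshold 0.9, accuracy 0.750 (2 pos / 2 neg)

ps <- precision_sensitivity(22, 20, 44)
lapply(ps, round, 2)
#> $precision  [1] 0.91
#> $sensitivity [1] 0.45
```

See the vignette (`vignettes/assessing-sa-scores.Rmd`) for the model, the
design decisions and the study scale.

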