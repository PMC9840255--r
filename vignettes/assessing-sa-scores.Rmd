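---
title: "Assessing synthetic-accessibility scores against retrosynthesis tree search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing synthetic-accessibility scores against retrosynthesis tree search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(retroassess)
```

## The question

Synthetic-accessibility (SA) scores are fast per-molecule estimates of how
easily a structure can be synthesized. They are used to prescreen large
candidate libraries before running a full computer-assisted synthesis
planning (CASP) search, which is orders of magnitude more expensive. Two
questions follow naturally: do SA scores *predict* the outcome of a
retrosynthesis planner, and could they *steer* the planner itself by
prioritising promising partial routes? `retroassess` implements the
machinery to answer both on a fully controlled testbed where the ground
truth is exactly computable.

## The planner

The planner is a template-based Monte Carlo tree search (MCTS). A node is a
partial solution: a multiset of molecules, each flagged in-stock or
expandable, each carrying the number of transformations it has undergone
from the target. The node's depth $m$ is the maximum of those transform
counts. One search round is:

1. **Selection.** From the root, repeatedly descend to the child maximising
   the upper confidence bound
   $$UCB = \frac{Q}{N_p} + 1.4\sqrt{\frac{2\ln N_{parent}}{N_p}},$$
   where $Q$ is the child's accumulated reward and $N_p$ its visit count.
   Unvisited children are taken before any visited sibling (the standard
   UCT convention: the formula is undefined at $N_p = 0$), ties broken by
   creation order.
2. **Expansion.** Every applicable (template, match position) pair on the
   first expandable molecule (lowest string order) produces one child in
   which the product molecule is replaced by its two precursors with
   transform count incremented. The planner this package analyses ranks
   template applications with a trained network; here expansion is
   exhaustive deterministic enumeration instead, which removes the
   trained-weights dependency while preserving the tree-search semantics.
3. **Rollout.** Greedy first-child descent until the node is solved (all
   molecules in stock), dead (no applicable template) or depth-capped
   ($m \ge$ `max_transforms`). Rollout nodes are kept in the tree.
4. **Backpropagation.** The terminal node's reward
   $$r = c\,\mathcal{SA} + (0.95 - c)\frac{M_s}{M} +
     \frac{0.05}{1 + e^{m-4}}$$
   is added (with one visit) to every node on the path back to the root.
   $M$ is the number of molecules in the node and $M_s$ the number in
   stock. At $c = 0$ this is the planner's native reward; $c > 0$ replaces
   a fraction of the stock term with a unit-scaled SA score of the node,
   which is the mechanism under test in the reward-replacement sweep
   ($c \in \{0, \tfrac14, \tfrac24, \tfrac34\}\times 0.95$). The SA term
   is evaluated where the reward is evaluated — at the rollout-terminal
   node during backpropagation — matching the reading that rewards enter
   only through leaf-node backpropagation.

Because expansion and rollout are deterministic and the toy scores are
deterministic per molecule, a search tree is a pure function of
`(target, world, config)`; the test suite asserts structural equality of
repeated runs.

Defaults: `max_transforms = 6`, `iteration_limit = 100`,
`exploration_constant = 1.4`, reward weights `(0.95, 0.05)`. The depth and
iteration limits are explicit configuration in the magnitudes typical of
open-source CASP tools, not claims about any particular published run.

## The toy world and its oracle

Real chemistries need trained expansion policies and externally trained
score models; none of the claims about search *trees* and their
*statistics* depend on chemistry, so the testbed replaces molecules by
non-empty strings over a small alphabet. A template rewrites a contiguous
pattern (length 2–3) into two fragments: matching `left P right` yields
precursors `left + part1` and `part2 + right`. Both fragments are
non-empty and shorter than the pattern, so every precursor is strictly
shorter than its product: all routes terminate, and an exact brute-force
oracle (`oracle_min_depth()`) can compute each molecule's minimal
synthesis depth by memoised exhaustive recursion. Worlds sample the stock
first and templates independently, so some targets are genuinely
unsynthesizable — the assessment needs both classes.

Two built-in molecule scores bracket the achievable range:

* `oracle_score()` — $\max(0, 1 - d/(D+1))$ for minimal depth $d$ and cap
  $D$, 0 when unsynthesizable: the best-informed score possible, strictly
  monotone in true difficulty. Any strictly monotone mapping would do;
  this one is pinned for reproducibility.
* `noise_score()` — deterministic per (molecule, seed), marginally uniform
  on $[0,1]$: the uninformative negative control.

What the toy world does **not** emulate: valence, stereochemistry,
reaction feasibility, the heavy-tailed branching of real template
libraries, and trained-policy ranking. Passing tests therefore demonstrate
the correctness and statistical behaviour of the *assessment machinery*
under a controlled generative model — not the real-world performance of
any published score, which requires the external score implementations and
a production planner.

## Node taxonomy and tree statistics

After a search, every node is classified:

* **solved** — a leaf whose molecules are all in stock (a complete route);
* **not solved** — no solved leaf is reachable from it (including itself);
* **internal** — the rest: it lies on a path to a solved leaf.

If the root is not solved, the search failed. All descendants of a
not-solved node are not solved, so the *roots* of not-solved subtrees are
where a prioritisation heuristic could have pruned earliest; pair
analyses default to those roots. A depth-capped leaf with all molecules in
stock is still solved (stock membership dominates), and dead-end nodes are
not solved regardless of depth.

Tree complexity is summarised by node count, maximum level width (the
supplementary-table sense of "tree width" — graph-theoretic treewidth of a
tree is trivially 1), and the number of not-solved leaves. Levels are
0-based distances from the root, distinct from the node's transform-depth
field.

## Scores on nodes

Raw scores are first mapped to $[0,1]$ with 1 = easily synthesizable
(`normalize_score()`): linear for the bounded published scales (the
familiar 1–10 fragment-based score maps as $(10 - raw)/9$, the 1–5
complexity scale as $(5-raw)/4$, probability-like scores pass through),
logistic with configurable scale $\tau = 10$ for unbounded log-odds. Only
the target range and orientation are prescribed by convention; linearity
is a design choice that is harmless for every rank-based statistic
downstream (AUC, Spearman), though threshold *values* do depend on it.

A node's score is the minimum, mean or maximum of its molecules' scores,
optionally over expandable molecules only. A solved node has no expandable
molecules; under the expandable-only variant its score is defined as 1 and
flagged, so analyses can drop such nodes. Minimum detects infeasible
outliers, maximum reports the easiest molecule; this is why informative
scores discriminate through min/mean but not max — a pattern the test
suite reproduces with the oracle score.

One subtlety decided here: the chance-level check for the noise control
uses the **mean** aggregation. The minimum of $k$ uniform variates is
stochastically smaller the larger $k$; node sizes differ systematically
between classes, so min-aggregated noise carries a node-size artifact and
sits off 0.5 without any per-molecule information. The mean of $k$
uniforms stays centred at 0.5 for every $k$, making it the clean null.

## The assessment suite

* `roc_curve()` sweeps thresholds over observed scores; AUC by trapezoid;
  the operating point maximises Youden's $J$ (the "best balance of
  sensitivity and specificity"), ties resolved toward the higher
  threshold; accuracy is reported at that point.
* `auc_pairwise()` computes the same quantity as the probability that a
  random positive outscores a random negative (ties half credit). The two
  implementations are kept as mutual oracles and must agree to $10^{-12}$.
* `spearman_corr()` — Pearson correlation of mid-ranks with a two-sided
  t-approximation p-value ($n-2$ df), exact permutation null available for
  small untied samples; used for score vs tree-complexity correlations.
* `paired_one_sided_t()` — one-sample t-test of pair differences against
  the alternative *mean > 0*, applied to (internal, not-solved) sibling
  pairs and to internal-parent / not-solved-child pairs.
* `discrimination_report()` pools nodes across trees (all not-solved
  nodes by default, matching how the pooled node analysis collects every
  node; the subtree-root restriction is available by flag) and tabulates
  AUCs for internal-vs-not-solved and solved-vs-not-solved per
  (score, statistic).
* `precision_sensitivity()` — route-finding precision and sensitivity from
  found/known route counts; rounding only at the reporting layer.

No multiple-testing correction is applied anywhere: raw p-values are
reported, as is conventional for this kind of benchmark heat-map.

## Study scale and numerical choices

The packaged experiments run on worlds with a 4-letter alphabet, 20
templates and a 30-molecule stock (lengths $\le 3$); target panels are
100–140 random strings of length 2–6. At that scale a 500-iteration search
takes milliseconds, the full acceptance script a few seconds, and the test
suite well under a minute — while the pooled node counts (several hundred
per class) are large enough for the stochastic checks to be stable across
seeds. The suite verifies, among others: the planner never claims a route
the oracle rules out; it recovers $\ge 95\%$ of oracle-feasible targets at
500 iterations; oracle-score min/mean aggregations discriminate internal
from not-solved nodes with AUC $\ge 0.9$ while mean-aggregated noise stays
within $0.5 \pm 0.07$; and internal siblings outscore their not-solved
pairs (one-sided $p < 0.01$).

Other pinned numerical choices: template pattern sites split after
$\lceil L/2 \rceil$ during generation; expansion order is template id then
match position; duplicate molecules in a node are kept as a multiset
($M$ counts occurrences); AUC ties get half credit; degenerate inputs
(constant correlation vectors, zero-variance differences, empty ROC
classes) raise errors rather than returning silent values, except where a
table cell is the natural unit (an empty class yields an `NA` cell).

## A worked run

```{r}
world <- generate_world(alphabet_size = 4, n_templates = 20,
                        stock_size = 30, stock_max_len = 3, seed = 1)
world
tree <- mcts_search("abca", world, planner_config(iteration_limit = 100))
tree
labels <- classify_nodes(tree)
table(labels)
tree_stats(tree, labels)
oracle_min_depth(world, "abca")
```

## Limitations

The toy chemistry's branching factors are modest and its score scales
coarse, so threshold-level results (best thresholds, accuracies) are
specific to the generative model and should not be read across to real
compound sets. Reproducing published benchmark values on real compounds
requires the trained score implementations and a production planner, and
is out of scope here; the package instead guarantees the ingestion path
for externally computed score tables and the correctness of every
statistic applied to them.
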