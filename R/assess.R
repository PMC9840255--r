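#' ROC curve with Youden-optimal threshold
#'
#' Sweeps the decision threshold over the union of observed scores (a case
#' is called positive when its score is >= the threshold), yielding TPR and
#' FPR arrays that run from (0, 0) to (1, 1). AUC is computed by the
#' trapezoid rule. The operating threshold is the maximiser of Youden's J
#' (sensitivity + specificity - 1), with ties broken toward the higher
#' threshold, and accuracy is reported at that threshold.
#'
#' @param pos_scores scores of the positive class (e.g. synthesizable /
#'   internal), higher = more positive.
#' @param neg_scores scores of the negative class.
#' @return list of class `roc_result` with `thresholds` (descending,
#'   starting at `Inf`), `tpr`, `fpr`, `auc`, `best_threshold`,
#'   `accuracy_at_best`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L)
    stop("both classes must be non-empty")
  stopifnot(all(is.finite(pos_scores)), all(is.finite(neg_scores)))
  thr <- c(Inf, sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(pos_scores >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg_scores >= t), numeric(1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  j <- tpr - fpr
  best_i <- which.max(j[-1L]) + 1L  # thresholds descending: first max = highest
  best <- thr[best_i]
  acc <- (sum(pos_scores >= best) + sum(neg_scores < best)) /
    (length(pos_scores) + length(neg_scores))
  structure(
    list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
         best_threshold = best, accuracy_at_best = acc,
         n_pos = length(pos_scores), n_neg = length(neg_scores)),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.3f, best threshold %.4g, accuracy %.3f (%d pos / %d neg)\n",
              x$auc, x$best_threshold, x$accuracy_at_best, x$n_pos, x$n_neg))
  invisible(x)
}

#' Pairwise-probability AUC
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with half credit for ties: the mean over all
#' pos x neg pairs of (1 if pos > neg, 1/2 if equal, 0 otherwise),
#' computed via mid-ranks. Must agree with the trapezoid AUC of
#' [roc_curve()] on every input — the two routes are kept as mutual
#' cross-checks.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
auc_pairwise <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L)
    stop("both classes must be non-empty")
  np <- length(pos_scores)
  r <- rank(c(pos_scores, neg_scores))  # mid-ranks on ties
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(neg_scores))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks; the two-sided p-value uses the
#' t-approximation with n - 2 degrees of freedom (adequate at the dozens
#' of observations typical here). For small samples without ties an exact
#' p-value is available via `exact = TRUE`.
#'
#' @param x,y numeric vectors of equal length >= 4; ties allowed.
#' @param exact use the exact null distribution (only for `n <= 10` and no
#'   ties; falls back to the t-approximation otherwise).
#' @return list of class `corr_result` with `rho`, `p_value`, `n`.
#' @export
spearman_corr <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4L) stop("need at least 4 observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("correlation undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  no_ties <- !anyDuplicated(x) && !anyDuplicated(y)
  if (exact && n <= 10L && no_ties) {
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  } else {
    denom <- 1 - rho^2
    if (denom < .Machine$double.eps) {
      p <- .Machine$double.xmin
    } else {
      tt <- rho * sqrt((n - 2) / denom)
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
  }
  structure(list(rho = rho, p_value = max(min(p, 1), .Machine$double.xmin),
                 n = n),
            class = "corr_result")
}

#' @export
print.corr_result <- function(x, ...) {
  cat(sprintf("spearman rho = %.3f (p = %.3g, n = %d)\n", x$rho, x$p_value, x$n))
  invisible(x)
}

#' One-sided paired t-test on score differences
#'
#' One-sample t-test of paired differences against the upper-tail
#' alternative that the mean difference is greater than 0 — the direction
#' in which an informative score rates internal nodes above their
#' not-solved counterparts. `t = mean / (sd / sqrt(n))`, p from Student's t
#' with n - 1 degrees of freedom.
#'
#' @param diffs numeric vector of pair differences
#'   (e.g. internal minus not-solved), length >= 2, non-degenerate.
#' @return list of class `paired_test_result` with `n_pairs`, `mean_diff`,
#'   `t_stat`, `p_one_sided`.
#' @export
paired_one_sided_t <- function(diffs) {
  n <- length(diffs)
  if (n < 2L) stop("need at least 2 pairs")
  s <- stats::sd(diffs)
  if (s == 0) stop("degenerate input: zero variance of differences")
  tt <- mean(diffs) / (s / sqrt(n))
  structure(
    list(n_pairs = n, mean_diff = mean(diffs), t_stat = tt,
         p_one_sided = stats::pt(tt, df = n - 1, lower.tail = FALSE)),
    class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("paired one-sided t: mean diff %.4f, t = %.3f, p = %.3g (n = %d)\n",
              x$mean_diff, x$t_stat, x$p_one_sided, x$n_pairs))
  invisible(x)
}

#' Route-finding precision and sensitivity
#'
#' Given the number of targets for which the planner found a route
#' (`n_found`), how many of those have a known route (`n_found_known`),
#' and how many targets have a known route in total (`n_known`):
#' precision = `n_found_known / n_found`,
#' sensitivity = `n_found_known / n_known`. Rounding (e.g. to 2 decimals)
#' belongs to the reporting layer, not here.
#'
#' @param n_found routes found by the planner.
#' @param n_found_known found routes that are known.
#' @param n_known known routes in total.
#' @return list with `precision` and `sensitivity`.
#' @export
precision_sensitivity <- function(n_found, n_found_known, n_known) {
  if (n_found <= 0 || n_known <= 0)
    stop("undefined metric: zero denominator")
  if (n_found_known < 0 || n_found_known > min(n_found, n_known))
    stop("need 0 <= n_found_known <= min(n_found, n_known)")
  list(precision = n_found_known / n_found,
       sensitivity = n_found_known / n_known)
}

#' Node-level discrimination AUC table
#'
#' Pools nodes across a collection of search trees and measures, per
#' (score, aggregation statistic), how well node scores separate internal
#' from not-solved nodes and solved from not-solved nodes (positive class
#' first). Trees lacking a class simply contribute nothing to it; a class
#' empty across all trees yields an `NA` cell rather than an error.
#'
#' @param trees list of `search_tree` objects (sharing one world).
#' @param score_names registered score names (default the toy controls
#'   `"oracle"` and `"noise"`).
#' @param statistics aggregation statistics to evaluate.
#' @param expandable_only aggregate node scores over expandable molecules
#'   only (nodes with an empty selection are excluded).
#' @param not_solved_roots restrict the not-solved class to roots of
#'   not-solved subtrees; the default (`FALSE`) pools all not-solved
#'   nodes, as the pooled discrimination analysis collects every node.
#' @param max_depth depth cap for the oracle score (default 6).
#' @param seed seed for sampling scores.
#' @return data.frame with one row per score x statistic x comparison:
#'   `score`, `statistic`, `comparison`, `auc`, `n_pos`, `n_neg`.
#' @export
discrimination_report <- function(trees, score_names = c("oracle", "noise"),
                                  statistics = c("min", "mean", "max"),
                                  expandable_only = FALSE,
                                  not_solved_roots = FALSE,
                                  max_depth = 6L, seed = 1L) {
  stopifnot(length(trees) >= 1L)
  labels <- lapply(trees, classify_nodes)
  world <- trees[[1]]$world
  rows <- list()
  for (sc in score_names) {
    scorer <- make_molecule_scorer(sc, world, max_depth = max_depth, seed = seed)
    for (st in statistics) {
      pools <- list(internal = numeric(0), solved = numeric(0),
                    not_solved = numeric(0))
      for (k in seq_along(trees)) {
        tr <- trees[[k]]
        lab <- labels[[k]]
        vals <- score_tree_nodes(tr, scorer, statistic = st,
                                 expandable_only = expandable_only)
        keep <- !attr(vals, "empty_selection")
        elig <- not_solved_eligible(tr, lab, not_solved_roots)
        pools$internal <- c(pools$internal, vals[lab == "internal" & keep])
        pools$solved <- c(pools$solved, vals[lab == "solved" & keep])
        pools$not_solved <- c(pools$not_solved, vals[elig & keep])
      }
      for (cmp in c("internal_vs_not_solved", "solved_vs_not_solved")) {
        pos <- pools[[sub("_vs.*", "", cmp)]]
        neg <- pools$not_solved
        auc <- if (length(pos) == 0L || length(neg) == 0L) NA_real_
               else auc_pairwise(pos, neg)
        rows[[length(rows) + 1L]] <-
          data.frame(score = sc, statistic = st, comparison = cmp,
                     auc = auc, n_pos = length(pos), n_neg = length(neg))
      }
    }
  }
  do.call(rbind, rows)
}
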