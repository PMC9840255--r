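#' Experiment configuration
#'
#' Bundles everything needed for the end-to-end workflow: plan a search
#' tree per target, classify its nodes, score them, run the statistical
#' assessment, and sweep the reward-replacement fraction `c`.
#'
#' @param world a [toy_world()].
#' @param targets character vector of target molecules.
#' @param planner a [planner_config()] used as the base (its
#'   `score_fraction_c` / `sa_score_name` are overridden by the sweep).
#' @param scores score names assessed on nodes and targets.
#' @param statistics aggregation statistics assessed.
#' @param c_values reward fractions swept; defaults to
#'   `c(0, 1, 2, 3) / 4 * 0.95` = (0, 0.2375, 0.475, 0.7125).
#' @param sweep_scores score(s) driving the reward replacement for
#'   `c > 0` (default `"oracle"`).
#' @param out_dir optional directory; when given, trees (JSON) and report
#'   tables (CSV/JSON) are written there.
#' @param seed integer seed threaded to every sampling score.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(world, targets,
                              planner = planner_config(),
                              scores = c("oracle", "noise"),
                              statistics = c("min", "mean", "max"),
                              c_values = c(0, 1, 2, 3) / 4 * 0.95,
                              sweep_scores = "oracle",
                              out_dir = NULL, seed = 1L) {
  stopifnot(inherits(world, "toy_world"), length(targets) >= 1L,
            inherits(planner, "planner_config"))
  if (any(c_values < 0 | c_values > planner$reward_weights[1]))
    stop("c_values must lie in [0, ", planner$reward_weights[1], "]")
  structure(list(world = world, targets = targets, planner = planner,
                 scores = scores, statistics = statistics,
                 c_values = sort(unique(c_values)),
                 sweep_scores = sweep_scores,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "experiment_config")
}

plan_targets <- function(world, targets, config) {
  lapply(targets, function(tg) mcts_search(tg, world, config))
}

stats_table <- function(trees, targets) {
  do.call(rbind, lapply(seq_along(trees), function(i) {
    cbind(data.frame(target = targets[i],
                     route_found = route_found(trees[[i]])),
          as.data.frame(tree_stats(trees[[i]])))
  }))
}

#' Run the full assessment experiment
#'
#' For the base planner (`c = 0`): plans one tree per target, classifies
#' nodes, and produces
#'
#' * `target_table` — per-target outcome, tree statistics and molecule
#'   scores;
#' * `roc_table` — per score, ROC/AUC of predicting the planner outcome
#'   from the target's molecule score (with Youden-optimal threshold and
#'   accuracy);
#' * `corr_table` — per score x complexity parameter, Spearman correlation
#'   between target scores and tree complexity;
#' * `discrimination` — pooled node-level AUC table
#'   ([discrimination_report()]);
#' * `sibling_tests`, `parent_child_tests` — one-sided paired t-tests on
#'   score differences over the node-pair configurations;
#' * `sweep_stats` — per-`c` (and sweep score) tree statistics for the
#'   reward-replacement sweep.
#'
#' The whole bundle is a pure function of `(config, seed)`. When
#' `out_dir` is set, trees are exported as JSON and tables as CSV, plus a
#' single JSON report.
#'
#' @param config an [experiment_config()].
#' @return list of class `experiment_report` with the tables above and
#'   `trees` (the base-run search trees).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  world <- config$world
  base_cfg <- config$planner
  base_cfg$score_fraction_c <- 0
  base_cfg$sa_score_name <- NULL
  base_cfg$seed <- config$seed
  trees <- plan_targets(world, config$targets, base_cfg)
  labels <- lapply(trees, classify_nodes)

  tt <- stats_table(trees, config$targets)
  scorers <- lapply(config$scores, function(sc)
    make_molecule_scorer(sc, world, max_depth = base_cfg$max_transforms,
                         seed = config$seed))
  names(scorers) <- config$scores
  for (sc in config$scores)
    tt[[paste0("score_", sc)]] <-
      vapply(config$targets, scorers[[sc]], numeric(1), USE.NAMES = FALSE)

  # outcome ROC per score (guard one-class outcomes)
  roc_rows <- lapply(config$scores, function(sc) {
    pos <- tt[[paste0("score_", sc)]][tt$route_found]
    neg <- tt[[paste0("score_", sc)]][!tt$route_found]
    if (length(pos) == 0L || length(neg) == 0L)
      return(data.frame(score = sc, auc = NA_real_, best_threshold = NA_real_,
                        accuracy = NA_real_, n_pos = length(pos),
                        n_neg = length(neg)))
    r <- roc_curve(pos, neg)
    data.frame(score = sc, auc = r$auc, best_threshold = r$best_threshold,
               accuracy = r$accuracy_at_best, n_pos = r$n_pos, n_neg = r$n_neg)
  })
  roc_table <- do.call(rbind, roc_rows)

  # Spearman of target score vs tree complexity
  corr_rows <- list()
  for (sc in config$scores) {
    for (par in c("n_nodes", "max_width", "n_not_solved_leaves")) {
      res <- tryCatch(spearman_corr(tt[[paste0("score_", sc)]], tt[[par]]),
                      error = function(e) NULL)
      corr_rows[[length(corr_rows) + 1L]] <-
        data.frame(score = sc, parameter = par,
                   rho = if (is.null(res)) NA_real_ else res$rho,
                   p_value = if (is.null(res)) NA_real_ else res$p_value,
                   n = nrow(tt))
    }
  }
  corr_table <- do.call(rbind, corr_rows)

  discrimination <- discrimination_report(
    trees, score_names = config$scores, statistics = config$statistics,
    max_depth = base_cfg$max_transforms, seed = config$seed)

  pair_tests <- function(pair_fun) {
    rows <- list()
    for (sc in config$scores) for (st in config$statistics) {
      diffs <- numeric(0)
      for (k in seq_along(trees)) {
        pr <- pair_fun(trees[[k]], labels[[k]])
        if (nrow(pr) == 0L) next
        vals <- score_tree_nodes(trees[[k]], scorers[[sc]], statistic = st)
        diffs <- c(diffs, vals[pr$internal_id] - vals[pr$not_solved_id])
      }
      res <- tryCatch(paired_one_sided_t(diffs), error = function(e) NULL)
      rows[[length(rows) + 1L]] <-
        data.frame(score = sc, statistic = st, n_pairs = length(diffs),
                   mean_diff = if (is.null(res)) NA_real_ else res$mean_diff,
                   t_stat = if (is.null(res)) NA_real_ else res$t_stat,
                   p_one_sided = if (is.null(res)) NA_real_ else res$p_one_sided)
    }
    do.call(rbind, rows)
  }
  sibling_tests <- pair_tests(sibling_pairs)
  parent_child_tests <- pair_tests(parent_child_pairs)

  # c sweep: tree complexity under partial reward replacement
  sweep_rows <- list()
  for (cc in config$c_values) {
    sw_scores <- if (cc == 0) NA_character_ else config$sweep_scores
    for (sw in sw_scores) {
      if (cc == 0) {
        sw_trees <- trees
      } else {
        cfg <- base_cfg
        cfg$score_fraction_c <- cc
        cfg$sa_score_name <- sw
        sw_trees <- plan_targets(world, config$targets, cfg)
      }
      st <- stats_table(sw_trees, config$targets)
      st$c <- cc
      st$sweep_score <- sw
      sweep_rows[[length(sweep_rows) + 1L]] <- st
    }
  }
  sweep_stats <- do.call(rbind, sweep_rows)

  report <- structure(
    list(target_table = tt, roc_table = roc_table, corr_table = corr_table,
         discrimination = discrimination, sibling_tests = sibling_tests,
         parent_child_tests = parent_child_tests, sweep_stats = sweep_stats,
         trees = trees, config = config),
    class = "experiment_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("experiment_report: %d targets, %d routes found, %d scores, c sweep {%s}\n",
              nrow(x$target_table), sum(x$target_table$route_found),
              length(x$config$scores),
              paste(signif(x$config$c_values, 4), collapse = ", ")))
  invisible(x)
}

#' Write an experiment report bundle to disk
#'
#' Trees as `trees/tree_<i>.json`, tables as CSV, and a combined
#' `report.json`.
#'
#' @param report an `experiment_report`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(file.path(out_dir, "trees"), recursive = TRUE,
             showWarnings = FALSE)
  for (i in seq_along(report$trees))
    write_tree(report$trees[[i]],
               file.path(out_dir, "trees", sprintf("tree_%03d.json", i)))
  tables <- c("target_table", "roc_table", "corr_table", "discrimination",
              "sibling_tests", "parent_child_tests", "sweep_stats")
  for (tb in tables)
    utils::write.csv(report[[tb]], file.path(out_dir, paste0(tb, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(report[tables], file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null",
                       dataframe = "rows")
  invisible(out_dir)
}
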