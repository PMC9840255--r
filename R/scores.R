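#' Score definitions and unit-interval rescaling
#'
#' All downstream analyses work on scores rescaled to `[0, 1]` with 1
#' meaning easily synthesizable and 0 infeasible. Built-in definitions:
#'
#' * `sascore` — raw range 1 (easy) to 10 (hard); rescaled `(10 - raw) / 9`.
#' * `scscore` — raw range 1 (simple) to 5 (complex); rescaled
#'   `(5 - raw) / 4`.
#' * `rascore` — already a unit-interval synthesizability probability;
#'   identity.
#' * `syba` — unbounded log-odds, positive = feasible; logistic squash
#'   `1 / (1 + exp(-raw / tau))` with `tau = 10` by default.
#' * `oracle`, `noise` — the toy world's built-in scores, already on
#'   `[0, 1]`; identity.
#'
#' Rank-based analyses (AUC, Spearman) are invariant to the particular
#' monotone rescaling; threshold values are not, which is why each mapping
#' is pinned here.
#'
#' @return named list of score definitions (`raw_range`, `orientation`,
#'   `transform`).
#' @export
score_defs <- function() {
  list(
    sascore = list(raw_range = c(1, 10), orientation = "lower_is_feasible",
                   transform = function(raw, ...) (10 - raw) / 9),
    scscore = list(raw_range = c(1, 5), orientation = "lower_is_feasible",
                   transform = function(raw, ...) (5 - raw) / 4),
    rascore = list(raw_range = c(0, 1), orientation = "higher_is_feasible",
                   transform = function(raw, ...) raw),
    syba = list(raw_range = c(-Inf, Inf), orientation = "higher_is_feasible",
                transform = function(raw, tau = 10, ...) 1 / (1 + exp(-raw / tau))),
    oracle = list(raw_range = c(0, 1), orientation = "higher_is_feasible",
                  transform = function(raw, ...) raw),
    noise = list(raw_range = c(0, 1), orientation = "higher_is_feasible",
                 transform = function(raw, ...) raw))
}

#' Rescale a raw score to the unit feasibility scale
#'
#' Values marginally outside the declared raw range (by at most `1e-9`,
#' e.g. from float round-off) are clamped; values further outside raise an
#' error naming the score.
#'
#' @param name score name, one of `names(score_defs())`.
#' @param raw numeric vector of raw values.
#' @param tau logistic scale for unbounded scores (default 10).
#' @return numeric vector in `[0, 1]`.
#' @export
normalize_score <- function(name, raw, tau = 10) {
  defs <- score_defs()
  if (!name %in% names(defs)) stop(sprintf("unknown score '%s'", name))
  def <- defs[[name]]
  lo <- def$raw_range[1]; hi <- def$raw_range[2]
  if (is.finite(lo) || is.finite(hi)) {
    if (any(raw < lo - 1e-9 | raw > hi + 1e-9))
      stop(sprintf("raw value outside the declared range [%g, %g] of score '%s'",
                   lo, hi, name))
    raw <- pmin(pmax(raw, lo), hi)
  }
  def$transform(raw, tau = tau)
}

# ---- molecule score plugins ----------------------------------------------

.score_registry <- new.env(parent = emptyenv())

#' Register a molecule score plugin
#'
#' A plugin is a function `fn(molecule, world, ...)` returning a raw value;
#' `transform` (if given) maps raw values to the unit feasibility scale.
#' The toy scores `"oracle"` and `"noise"` are pre-registered; external
#' published score implementations can be plugged in the same way and are
#' never required by the core.
#'
#' @param name plugin name.
#' @param fn scoring function.
#' @param transform optional rescaling function applied to `fn`'s output.
#' @return `name`, invisibly.
#' @export
register_score <- function(name, fn, transform = NULL) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, list(fn = fn, transform = transform), envir = .score_registry)
  invisible(name)
}

register_builtin_scores <- function() {
  register_score("oracle",
                 function(molecule, world, max_depth = 6L, memo = NULL, ...)
                   oracle_score(world, molecule, max_depth = max_depth, memo = memo))
  register_score("noise",
                 function(molecule, world = NULL, seed = 1L, ...)
                   noise_score(molecule, seed = seed))
}

#' Score a molecule through the plugin registry
#'
#' @param name registered plugin name.
#' @param molecule molecule string.
#' @param world a [toy_world()] (required by world-dependent scores such as
#'   `"oracle"`; ignored by others).
#' @param ... passed to the plugin (e.g. `max_depth`, `seed`).
#' @return unit-interval score.
#' @export
score_molecule <- function(name, molecule, world = NULL, ...) {
  if (!exists(name, envir = .score_registry, inherits = FALSE))
    stop(sprintf("unknown score '%s'; register it with register_score()", name))
  entry <- get(name, envir = .score_registry, inherits = FALSE)
  raw <- entry$fn(molecule, world = world, ...)
  if (is.null(entry$transform)) raw else entry$transform(raw)
}

#' Memoising molecule scorer
#'
#' Returns a closure `function(molecule) -> unit score` that caches per
#' molecule string — the form the planner and the node-scoring helpers
#' consume. The oracle plugin additionally shares one depth memo across all
#' molecules of the world.
#'
#' @param score_name registered score name.
#' @param world a [toy_world()].
#' @param max_depth depth cap for the oracle score.
#' @param seed seed for sampling scores such as `"noise"`.
#' @return function of one molecule string.
#' @export
make_molecule_scorer <- function(score_name, world, max_depth = 6L, seed = 1L) {
  cache <- new.env(parent = emptyenv())
  memo <- new.env(parent = emptyenv())
  function(molecule) {
    if (!exists(molecule, envir = cache, inherits = FALSE)) {
      v <- switch(score_name,
        oracle = oracle_score(world, molecule, max_depth = max_depth, memo = memo),
        noise = noise_score(molecule, seed = seed),
        score_molecule(score_name, molecule, world = world))
      assign(molecule, v, envir = cache)
    }
    get(molecule, envir = cache, inherits = FALSE)
  }
}

#' Aggregate per-molecule scores into a node score
#'
#' Applies one of the statistics minimum, arithmetic mean or maximum over
#' the molecules of a node, optionally restricted to expandable (not in
#' stock) molecules. A solved node has no expandable molecules; under
#' `expandable_only` its score is defined as 1 (a fully solved partial
#' route is maximally feasible) and flagged via `empty_selection` so
#' analyses can exclude such nodes.
#'
#' @param values unit-interval per-molecule scores.
#' @param statistic `"min"`, `"mean"` or `"max"`.
#' @param expandable logical vector marking expandable molecules (required
#'   when `expandable_only = TRUE`).
#' @param expandable_only restrict aggregation to expandable molecules.
#' @return list with `value`, `statistic`, `expandable_only`,
#'   `empty_selection`.
#' @export
node_score <- function(values, statistic = c("min", "mean", "max"),
                       expandable = NULL, expandable_only = FALSE) {
  statistic <- match.arg(statistic)
  stopifnot(length(values) >= 1L, all(values >= 0 & values <= 1))
  sel <- values
  if (expandable_only) {
    if (is.null(expandable) || length(expandable) != length(values))
      stop("expandable flags required when expandable_only = TRUE")
    sel <- values[expandable]
  }
  if (length(sel) == 0L)
    return(list(value = 1, statistic = statistic,
                expandable_only = expandable_only, empty_selection = TRUE))
  v <- switch(statistic, min = min(sel), mean = mean(sel), max = max(sel))
  list(value = v, statistic = statistic,
       expandable_only = expandable_only, empty_selection = FALSE)
}

#' Node scores for every node of a search tree
#'
#' @param tree a `search_tree`.
#' @param scorer molecule scorer closure from [make_molecule_scorer()].
#' @param statistic aggregation statistic (`"min"`, `"mean"`, `"max"`).
#' @param expandable_only aggregate over expandable molecules only.
#' @return numeric vector of node scores (one per node id) with attribute
#'   `empty_selection` flagging nodes whose selection was empty.
#' @export
score_tree_nodes <- function(tree, scorer, statistic = "mean",
                             expandable_only = FALSE) {
  n <- n_nodes(tree)
  vals <- numeric(n)
  empty <- logical(n)
  for (i in seq_len(n)) {
    mols <- tree$mols[[i]]
    mv <- vapply(mols$string, scorer, numeric(1), USE.NAMES = FALSE)
    ns <- node_score(mv, statistic = statistic,
                     expandable = !mols$in_stock,
                     expandable_only = expandable_only)
    vals[i] <- ns$value
    empty[i] <- ns$empty_selection
  }
  attr(vals, "empty_selection") <- empty
  vals
}
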