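#' Planner configuration
#'
#' Collects every tunable of the MCTS retrosynthesis search. The reward of a
#' terminal node is
#' `c * SA + (0.95 - c) * M_s / M + 0.05 / (1 + exp(m - 4))`,
#' where `M` is the number of molecules in the node, `M_s` the number of
#' them in stock, `m` the node depth (maximal per-molecule transform count)
#' and `SA` an aggregated, unit-scaled synthetic-accessibility score of the
#' node. At `c = 0` this is the planner's native reward; `c > 0` replaces a
#' fraction of the stock term with the SA score. Leaf selection maximises
#' `Q / N_p + 1.4 * sqrt(2 * ln(N_parent) / N_p)`.
#'
#' @param max_transforms depth threshold: a partial route whose deepest
#'   molecule has undergone this many transformations is not expanded
#'   further (default 6).
#' @param iteration_limit number of MCTS rounds (default 100).
#' @param exploration_constant multiplier of the exploration term
#'   (default 1.4).
#' @param reward_weights weights of the stock-fraction and depth-penalty
#'   terms (default `c(0.95, 0.05)`).
#' @param score_fraction_c fraction `c` of the reward replaced by an SA
#'   score, in `[0, 0.95]`; the sweep values of interest are
#'   `c(0, 1, 2, 3) / 4 * 0.95`.
#' @param sa_score_name registered score used when `score_fraction_c > 0`
#'   (e.g. `"oracle"`, `"noise"`); must be `NULL` when `c = 0`.
#' @param aggregation_statistic how per-molecule scores are pooled into a
#'   node score: `"min"`, `"mean"` or `"max"` (default `"mean"`).
#' @param expandable_only aggregate the SA score over expandable (not in
#'   stock) molecules only (default `FALSE`).
#' @param seed integer seed threaded to score plugins that sample.
#' @param stop_on_solve stop iterating once a solved leaf is reached
#'   (default `FALSE`; the full budget is spent, as when collecting search
#'   trees for analysis).
#' @return object of class `planner_config`.
#' @export
planner_config <- function(max_transforms = 6L, iteration_limit = 100L,
                           exploration_constant = 1.4,
                           reward_weights = c(0.95, 0.05),
                           score_fraction_c = 0,
                           sa_score_name = NULL,
                           aggregation_statistic = c("mean", "min", "max"),
                           expandable_only = FALSE,
                           seed = 1L,
                           stop_on_solve = FALSE) {
  aggregation_statistic <- match.arg(aggregation_statistic)
  if (max_transforms < 1L) stop("max_transforms must be >= 1")
  if (iteration_limit < 1L) stop("iteration_limit must be >= 1")
  if (length(reward_weights) != 2L || any(reward_weights < 0))
    stop("reward_weights must be two non-negative numbers")
  if (score_fraction_c < 0 || score_fraction_c > reward_weights[1])
    stop("score_fraction_c must lie in [0, ", reward_weights[1], "]")
  if (score_fraction_c > 0 && is.null(sa_score_name))
    stop("sa_score_name is required when score_fraction_c > 0")
  if (score_fraction_c == 0 && !is.null(sa_score_name))
    stop("sa_score_name must be NULL when score_fraction_c = 0")
  structure(
    list(max_transforms = as.integer(max_transforms),
         iteration_limit = as.integer(iteration_limit),
         exploration_constant = as.numeric(exploration_constant),
         reward_weights = as.numeric(reward_weights),
         score_fraction_c = as.numeric(score_fraction_c),
         sa_score_name = sa_score_name,
         aggregation_statistic = aggregation_statistic,
         expandable_only = isTRUE(expandable_only),
         seed = as.integer(seed),
         stop_on_solve = isTRUE(stop_on_solve)),
    class = "planner_config")
}

#' @export
print.planner_config <- function(x, ...) {
  cat(sprintf("planner_config: %d iterations, depth limit %d, c = %g%s\n",
              x$iteration_limit, x$max_transforms, x$score_fraction_c,
              if (is.null(x$sa_score_name)) ""
              else sprintf(" (%s, %s)", x$sa_score_name,
                           x$aggregation_statistic)))
  invisible(x)
}

#' Exploration term of the selection criterion
#'
#' `constant * sqrt(2 * ln(parent_visits) / child_visits)`; large for
#' under-visited children. Zero-visit children never reach this formula:
#' they are selected unconditionally by the visit-first rule.
#'
#' @param child_visits visit count of the child, >= 1.
#' @param parent_visits visit count of the parent, >= 1.
#' @param exploration_constant multiplier (default 1.4).
#' @return non-negative number.
#' @export
exploration_term <- function(child_visits, parent_visits,
                             exploration_constant = 1.4) {
  if (any(child_visits < 1) || any(parent_visits < 1))
    stop("visit counts must be >= 1")
  exploration_constant * sqrt(2 * log(parent_visits) / child_visits)
}

#' Upper confidence bound of a node
#'
#' `Q / N_p + U` where `Q` is the node's accumulated reward, `N_p` its
#' visit count and `U` the [exploration_term()] computed against the
#' parent's visit count.
#'
#' @param node,parent node lists (as returned by [get_node()]) carrying
#'   `total_reward` and `visit_count`.
#' @param exploration_constant multiplier (default 1.4).
#' @return UCB value.
#' @export
ucb <- function(node, parent, exploration_constant = 1.4) {
  if (node$visit_count < 1) stop("ucb undefined for unvisited nodes")
  node$total_reward / node$visit_count +
    exploration_term(node$visit_count, parent$visit_count,
                     exploration_constant)
}

#' Reward of a terminal node
#'
#' @param M number of molecules in the node (>= 1).
#' @param M_s number of those in stock (`0 <= M_s <= M`).
#' @param m node depth: the maximal number of transformations any molecule
#'   of the node has undergone from the target.
#' @param score_fraction fraction `c` replaced by the SA score (default 0).
#' @param sa_score aggregated node SA score in `[0, 1]`; required when
#'   `score_fraction > 0`.
#' @param reward_weights stock-term and depth-term weights
#'   (default `c(0.95, 0.05)`).
#' @return reward in `(0, 1]`.
#' @export
reward_value <- function(M, M_s, m, score_fraction = 0, sa_score = NULL,
                         reward_weights = c(0.95, 0.05)) {
  if (M < 1 || M_s < 0 || M_s > M) stop("need 0 <= M_s <= M, M >= 1")
  if (score_fraction > 0) {
    if (is.null(sa_score)) stop("sa_score required when score_fraction > 0")
    if (sa_score < 0 || sa_score > 1) stop("sa_score must lie in [0, 1]")
  }
  sa <- if (is.null(sa_score)) 0 else sa_score
  score_fraction * sa + (reward_weights[1] - score_fraction) * M_s / M +
    reward_weights[2] / (1 + exp(m - 4))
}

# ---- search tree container ------------------------------------------------
# The tree is an environment holding parallel per-node vectors; node ids are
# dense integers in creation order, so a parent's id is always smaller than
# its children's. status: "open" (expandable, not yet expanded), "expanded",
# "solved" (all molecules in stock), "depth_capped", "dead_end".

new_search_tree <- function(target, world, config) {
  tree <- new.env(parent = emptyenv())
  tree$world <- world
  tree$config <- config
  tree$parent <- integer(0)
  tree$children <- list()
  tree$depth <- integer(0)
  tree$visit_count <- numeric(0)
  tree$total_reward <- numeric(0)
  tree$mols <- list()
  tree$reaction <- list()
  tree$status <- character(0)
  class(tree) <- "search_tree"
  add_node(tree, parent = 0L,
           mols = list(string = target,
                       in_stock = target %in% world$stock,
                       transforms = 0L),
           reaction = NULL)
  tree
}

add_node <- function(tree, parent, mols, reaction) {
  id <- length(tree$status) + 1L
  depth <- max(mols$transforms)
  status <- if (!any(!mols$in_stock)) "solved"
            else if (depth >= tree$config$max_transforms) "depth_capped"
            else "open"
  tree$parent[id] <- parent
  tree$children[[id]] <- integer(0)
  tree$depth[id] <- as.integer(depth)
  tree$visit_count[id] <- 0
  tree$total_reward[id] <- 0
  tree$mols[[id]] <- mols
  tree$reaction[id] <- list(reaction)
  tree$status[id] <- status
  if (parent > 0L)
    tree$children[[parent]] <- c(tree$children[[parent]], id)
  id
}

#' Number of nodes in a search tree
#' @param tree a `search_tree`.
#' @return integer.
#' @export
n_nodes <- function(tree) length(tree$status)

#' Snapshot of a single search node
#'
#' @param tree a `search_tree`.
#' @param id node id (dense integer, creation order; the root is 1).
#' @return list with `node_id`, `parent_id` (0 for the root), `depth`,
#'   `visit_count`, `total_reward`, `status`, `children`, `molecules`
#'   (`string`, `in_stock`, `transforms` vectors) and `incoming_reaction`
#'   (`NULL` for the root).
#' @export
get_node <- function(tree, id) {
  stopifnot(id >= 1L, id <= n_nodes(tree))
  list(node_id = id,
       parent_id = tree$parent[id],
       depth = tree$depth[id],
       visit_count = tree$visit_count[id],
       total_reward = tree$total_reward[id],
       status = tree$status[id],
       children = tree$children[[id]],
       molecules = tree$mols[[id]],
       incoming_reaction = tree$reaction[[id]])
}

#' @export
print.search_tree <- function(x, ...) {
  cat(sprintf("search_tree: %d nodes, root '%s', route %s (%d solved leaves)\n",
              n_nodes(x), x$mols[[1]]$string[1],
              if (route_found(x)) "found" else "not found",
              sum(x$status == "solved")))
  invisible(x)
}

#' Was a complete route found?
#' @param tree a `search_tree`.
#' @return `TRUE` iff the tree contains a solved leaf (a node whose
#'   molecules are all in stock).
#' @export
route_found <- function(tree) any(tree$status == "solved")

#' Select a leaf by recursive UCB descent
#'
#' Starting from the root, descends to the child of maximal UCB at every
#' expanded node; unvisited children are selected before any visited
#' sibling (ties broken by creation order). Stops at the first node without
#' children: an expandable node awaiting expansion, or a terminal
#' (solved / depth-capped / dead-end) leaf.
#'
#' @param tree a `search_tree`.
#' @return the selected node id.
#' @export
select_leaf <- function(tree) {
  id <- 1L
  cexp <- tree$config$exploration_constant
  while (tree$status[id] == "expanded") {
    kids <- tree$children[[id]]
    vis <- tree$visit_count[kids]
    if (any(vis == 0)) {
      id <- kids[which(vis == 0)[1L]]
      next
    }
    u <- tree$total_reward[kids] / vis +
      cexp * sqrt(2 * log(tree$visit_count[id]) / vis)
    id <- kids[which.max(u)]
  }
  id
}

#' Expand a node
#'
#' Applies every matching (template, position) pair to the node's first
#' expandable molecule (lowest string order; first occurrence on ties) and
#' creates one child per applicable reaction, replacing the product molecule
#' by its two precursors with transform count incremented. Children start
#' with zero visits and zero reward. If no template applies, the node is
#' marked a dead end and no children are created.
#'
#' @param tree a `search_tree`.
#' @param id id of an expandable (`"open"`) node.
#' @return integer vector of new child ids (possibly empty).
#' @export
expand_node <- function(tree, id) {
  if (tree$status[id] != "open")
    stop("expand_node requires an expandable node")
  mols <- tree$mols[[id]]
  exp_idx <- which(!mols$in_stock)
  pick <- exp_idx[order(mols$string[exp_idx])[1L]]
  apps <- apply_templates(tree$world, mols$string[pick])
  if (length(apps) == 0L) {
    tree$status[id] <- "dead_end"
    return(integer(0))
  }
  tree$status[id] <- "expanded"
  t_new <- mols$transforms[pick] + 1L
  keep <- seq_along(mols$string)[-pick]
  kids <- integer(length(apps))
  for (k in seq_along(apps)) {
    a <- apps[[k]]
    child_mols <- list(
      string = c(mols$string[keep], a$precursors),
      in_stock = c(mols$in_stock[keep], a$precursors %in% tree$world$stock),
      transforms = c(mols$transforms[keep], rep(t_new, 2L)))
    kids[k] <- add_node(tree, id, child_mols,
                        reaction = list(template_id = a$template_id,
                                        position = a$position,
                                        product = mols$string[pick],
                                        precursors = a$precursors))
  }
  kids
}

#' Rollout: greedy simulation to a terminal node
#'
#' From the given node, repeatedly expands and descends into the first
#' child (deterministic greedy descent) until the node is solved, has no
#' applicable template, or is depth-capped. All nodes created on the way
#' are kept in the tree.
#'
#' @param tree a `search_tree`.
#' @param id starting node id.
#' @return id of the terminal node reached (the node itself if already
#'   terminal).
#' @export
rollout <- function(tree, id) {
  while (tree$status[id] == "open") {
    kids <- expand_node(tree, id)
    if (length(kids) == 0L) break
    id <- kids[1L]
  }
  id
}

#' Backpropagate a reward
#'
#' Adds one visit and the reward to every node on the path from the
#' terminal node to the root.
#'
#' @param tree a `search_tree`.
#' @param id terminal node id.
#' @param reward reward value in `[0, 1]`.
#' @return the tree, invisibly.
#' @export
backpropagate <- function(tree, id, reward) {
  if (reward < 0 || reward > 1) stop("reward must lie in [0, 1]")
  while (id > 0L) {
    tree$visit_count[id] <- tree$visit_count[id] + 1
    tree$total_reward[id] <- tree$total_reward[id] + reward
    id <- tree$parent[id]
  }
  invisible(tree)
}

node_reward <- function(tree, id, config, mol_scorer) {
  mols <- tree$mols[[id]]
  sa <- NULL
  if (config$score_fraction_c > 0) {
    vals <- vapply(mols$string, mol_scorer, numeric(1), USE.NAMES = FALSE)
    sa <- node_score(vals, statistic = config$aggregation_statistic,
                     expandable = !mols$in_stock,
                     expandable_only = config$expandable_only)$value
  }
  reward_value(M = length(mols$string), M_s = sum(mols$in_stock),
               m = tree$depth[id],
               score_fraction = config$score_fraction_c, sa_score = sa,
               reward_weights = config$reward_weights)
}

#' MCTS retrosynthesis search
#'
#' Runs `iteration_limit` rounds of select / expand / rollout /
#' backpropagate from the target molecule. Expansion is exhaustive
#' deterministic template enumeration (no trained ranking policy), rollout
#' is greedy first-child descent, and the reward is evaluated at the
#' rollout-terminal node, so the whole search is a pure function of
#' `(target, world, config)`.
#'
#' @param target target molecule string (canonical, i.e. as written).
#' @param world a [toy_world()].
#' @param config a [planner_config()].
#' @return a `search_tree`; check [route_found()] for the outcome.
#' @export
mcts_search <- function(target, world, config = planner_config()) {
  stopifnot(inherits(world, "toy_world"), inherits(config, "planner_config"))
  ok <- all(strsplit(target, "")[[1]] %in% world$alphabet)
  if (!ok) stop("target contains symbols outside the world alphabet")
  tree <- new_search_tree(target, world, config)
  mol_scorer <- if (config$score_fraction_c > 0) {
    make_molecule_scorer(config$sa_score_name, world,
                         max_depth = config$max_transforms,
                         seed = config$seed)
  }
  for (iter in seq_len(config$iteration_limit)) {
    leaf <- select_leaf(tree)
    terminal <- leaf
    if (tree$status[leaf] == "open") {
      kids <- expand_node(tree, leaf)
      if (length(kids) > 0L) terminal <- rollout(tree, kids[1L])
    }
    backpropagate(tree, terminal, node_reward(tree, terminal, config, mol_scorer))
    if (config$stop_on_solve && tree$status[terminal] == "solved") break
  }
  tree
}
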