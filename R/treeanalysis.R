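#' Classify search-tree nodes
#'
#' Every node gets exactly one label:
#'
#' * `solved` — a leaf whose molecules are all in stock (a complete route).
#' * `not_solved` — a node from which no solved leaf is reachable
#'   (including itself); the roots of such subtrees are the earliest points
#'   at which a search branch is provably wasted.
#' * `internal` — every other node: it lies on a path to a solved leaf.
#'
#' If the root is `not_solved` the search found no route at all.
#' Implemented as a single bottom-up pass (children have larger ids than
#' their parents by construction).
#'
#' @param tree a `search_tree`.
#' @return character vector of labels indexed by node id.
#' @export
classify_nodes <- function(tree) {
  n <- n_nodes(tree)
  kids <- tree$children[seq_len(n)]
  leaf <- lengths(kids) == 0L
  solved <- vapply(seq_len(n),
                   function(i) leaf[i] && all(tree$mols[[i]]$in_stock),
                   logical(1))
  reach <- logical(n)
  for (i in rev(seq_len(n)))
    reach[i] <- solved[i] || any(reach[kids[[i]]])
  ifelse(solved, "solved", ifelse(reach, "internal", "not_solved"))
}

# 0-based level of each node (distance from the root), in id order.
node_levels <- function(tree) {
  n <- n_nodes(tree)
  lev <- integer(n)
  for (i in seq_len(n)[-1L])
    lev[i] <- lev[tree$parent[i]] + 1L
  lev
}

#' Search-tree complexity statistics
#'
#' Node count, maximum level width (the largest number of nodes at any
#' distance from the root — the "tree width" of the search tree, not
#' graph-theoretic treewidth), numbers of not-solved and solved leaves,
#' and the maximum level depth.
#'
#' @param tree a `search_tree`.
#' @param labels labels from [classify_nodes()] on the same tree.
#' @return list of class `tree_stats` with `n_nodes`, `max_width`,
#'   `n_not_solved_leaves`, `n_solved_leaves`, `max_depth`.
#' @export
tree_stats <- function(tree, labels = classify_nodes(tree)) {
  n <- n_nodes(tree)
  if (length(labels) != n)
    stop("labels do not match the tree (wrong length)")
  lev <- node_levels(tree)
  leaf <- lengths(tree$children[seq_len(n)]) == 0L
  structure(
    list(n_nodes = n,
         max_width = max(tabulate(lev + 1L)),
         n_not_solved_leaves = sum(leaf & labels == "not_solved"),
         n_solved_leaves = sum(labels == "solved"),
         max_depth = max(lev)),
    class = "tree_stats")
}

#' @export
print.tree_stats <- function(x, ...) {
  cat(sprintf("tree_stats: %d nodes, width %d, depth %d, %d solved / %d not-solved leaves\n",
              x$n_nodes, x$max_width, x$max_depth,
              x$n_solved_leaves, x$n_not_solved_leaves))
  invisible(x)
}

#' @export
as.data.frame.tree_stats <- function(x, ...) {
  data.frame(n_nodes = x$n_nodes, max_width = x$max_width,
             n_not_solved_leaves = x$n_not_solved_leaves,
             n_solved_leaves = x$n_solved_leaves, max_depth = x$max_depth)
}

# not_solved nodes eligible for pair analyses: by default only the topmost
# node of each not_solved subtree (its parent is not itself not_solved).
not_solved_eligible <- function(tree, labels, not_solved_roots) {
  ns <- labels == "not_solved"
  if (!not_solved_roots) return(ns)
  par <- tree$parent
  ns & (par == 0L | labels[pmax(par, 1L)] != "not_solved")
}

#' Internal / not-solved sibling pairs
#'
#' All (internal, not_solved) pairs of children of the same internal
#' parent: the configurations in which a score, had it prioritised nodes,
#' could have steered the search away from a wasted branch at the moment
#' of choice. By default the not-solved member must be the root of its
#' not-solved subtree (`not_solved_roots = TRUE`); deeper not-solved nodes
#' carry no extra information since all their descendants are not solved
#' too.
#'
#' @param tree a `search_tree`.
#' @param labels labels from [classify_nodes()].
#' @param not_solved_roots restrict not-solved pair members to subtree
#'   roots (default `TRUE`).
#' @return data.frame with columns `kind`, `parent_id`, `internal_id`,
#'   `not_solved_id`, in deterministic (ascending id) order.
#' @export
sibling_pairs <- function(tree, labels = classify_nodes(tree),
                          not_solved_roots = TRUE) {
  elig <- not_solved_eligible(tree, labels, not_solved_roots)
  rows <- list()
  for (p in which(labels == "internal")) {
    kids <- tree$children[[p]]
    if (length(kids) < 2L) next
    ints <- kids[labels[kids] == "internal"]
    nss <- kids[elig[kids]]
    if (length(ints) == 0L || length(nss) == 0L) next
    for (i in ints) for (s in nss)
      rows[[length(rows) + 1L]] <-
        data.frame(kind = "siblings", parent_id = p,
                   internal_id = i, not_solved_id = s)
  }
  if (length(rows) == 0L)
    return(data.frame(kind = character(0), parent_id = integer(0),
                      internal_id = integer(0), not_solved_id = integer(0)))
  do.call(rbind, rows)
}

#' Internal-parent / not-solved-child pairs
#'
#' All directly linked pairs of an internal parent and a not-solved child
#' (the not-solved child is necessarily the root of its not-solved
#' subtree).
#'
#' @inheritParams sibling_pairs
#' @return data.frame with columns `kind`, `parent_id`, `internal_id`
#'   (the parent), `not_solved_id` (the child).
#' @export
parent_child_pairs <- function(tree, labels = classify_nodes(tree),
                               not_solved_roots = TRUE) {
  elig <- not_solved_eligible(tree, labels, not_solved_roots)
  rows <- list()
  for (p in which(labels == "internal")) {
    for (s in tree$children[[p]][elig[tree$children[[p]]]])
      rows[[length(rows) + 1L]] <-
        data.frame(kind = "parent_child", parent_id = p,
                   internal_id = p, not_solved_id = s)
  }
  if (length(rows) == 0L)
    return(data.frame(kind = character(0), parent_id = integer(0),
                      internal_id = integer(0), not_solved_id = integer(0)))
  do.call(rbind, rows)
}
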