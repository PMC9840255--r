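TREE_SCHEMA_VERSION <- "1.0"

#' Serialize a toy world
#'
#' @param world a [toy_world()].
#' @return plain list mirroring the JSON schema
#'   `{alphabet_size, templates:[{id, pattern, parts}], stock, seed}`.
#' @export
world_to_list <- function(world) {
  list(alphabet_size = world$alphabet_size,
       templates = lapply(world$templates, function(t)
         list(id = t$template_id, pattern = t$pattern,
              parts = as.list(t$parts))),
       stock = as.list(world$stock),
       seed = if (is.na(world$seed)) NULL else world$seed)
}

world_from_list <- function(doc) {
  toy_world(alphabet_size = doc$alphabet_size,
            templates = lapply(doc$templates, function(t)
              list(template_id = as.integer(t$id), pattern = t$pattern,
                   parts = unlist(t$parts))),
            stock = unlist(doc$stock),
            seed = if (is.null(doc$seed)) NA_integer_ else doc$seed)
}

#' Write / read a toy world as JSON
#'
#' @param world a [toy_world()].
#' @param path file path.
#' @return `write_world` returns `path` invisibly; `read_world` returns a
#'   [toy_world()].
#' @export
write_world <- function(world, path) {
  jsonlite::write_json(world_to_list(world), path, auto_unbox = TRUE,
                       digits = I(17), null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_world
#' @export
read_world <- function(path) {
  world_from_list(jsonlite::fromJSON(path, simplifyVector = FALSE))
}

#' Export a search tree to a plain document
#'
#' The document is self-contained (config and world embedded) and
#' round-trips losslessly through [import_tree()].
#'
#' @param tree a `search_tree`.
#' @return plain list following the tree JSON schema.
#' @export
export_tree <- function(tree) {
  n <- n_nodes(tree)
  nodes <- vector("list", n)
  for (i in seq_len(n)) {
    mols <- tree$mols[[i]]
    rx <- tree$reaction[[i]]
    nodes[[i]] <- list(
      id = i,
      parent = tree$parent[i],
      depth = tree$depth[i],
      visits = tree$visit_count[i],
      total_reward = tree$total_reward[i],
      status = tree$status[i],
      molecules = lapply(seq_along(mols$string), function(j)
        list(string = mols$string[j], in_stock = mols$in_stock[j],
             transforms = mols$transforms[j])),
      reaction = if (is.null(rx)) NULL
                 else list(template_id = rx$template_id,
                           position = rx$position,
                           product = rx$product,
                           precursors = as.list(rx$precursors)))
  }
  cfg <- unclass(tree$config)
  list(schema_version = TREE_SCHEMA_VERSION,
       config = cfg,
       world = world_to_list(tree$world),
       nodes = nodes)
}

config_from_list <- function(cfg) {
  planner_config(
    max_transforms = cfg$max_transforms,
    iteration_limit = cfg$iteration_limit,
    exploration_constant = as.numeric(cfg$exploration_constant),
    reward_weights = as.numeric(unlist(cfg$reward_weights)),
    score_fraction_c = as.numeric(cfg$score_fraction_c),
    sa_score_name = cfg$sa_score_name,
    aggregation_statistic = cfg$aggregation_statistic,
    expandable_only = isTRUE(cfg$expandable_only),
    seed = cfg$seed,
    stop_on_solve = isTRUE(cfg$stop_on_solve))
}

#' Rebuild a search tree from an exported document
#'
#' Validates the schema version and the structural invariants (dense ids,
#' parents precede children, root at id 1); a malformed or truncated
#' document raises an error and no partial tree is returned.
#'
#' @param doc list as produced by [export_tree()] (or parsed from its
#'   JSON form).
#' @return a `search_tree`.
#' @export
import_tree <- function(doc) {
  if (is.null(doc$schema_version) || doc$schema_version != TREE_SCHEMA_VERSION)
    stop(sprintf("tree schema mismatch: expected %s, got %s",
                 TREE_SCHEMA_VERSION,
                 ifelse(is.null(doc$schema_version), "none",
                        doc$schema_version)))
  if (is.null(doc$nodes) || length(doc$nodes) == 0L)
    stop("tree document has no nodes")
  world <- world_from_list(doc$world)
  config <- config_from_list(doc$config)
  tree <- new.env(parent = emptyenv())
  tree$world <- world
  tree$config <- config
  n <- length(doc$nodes)
  tree$parent <- integer(n)
  tree$children <- rep(list(integer(0)), n)
  tree$depth <- integer(n)
  tree$visit_count <- numeric(n)
  tree$total_reward <- numeric(n)
  tree$mols <- vector("list", n)
  tree$reaction <- vector("list", n)
  tree$status <- character(n)
  for (i in seq_len(n)) {
    nd <- doc$nodes[[i]]
    if (is.null(nd$id) || nd$id != i)
      stop("tree document ids must be dense and in creation order")
    par <- as.integer(nd$parent)
    if (i == 1L && par != 0L) stop("root must have parent 0")
    if (i > 1L && (par < 1L || par >= i))
      stop("parents must precede their children")
    tree$parent[i] <- par
    tree$depth[i] <- as.integer(nd$depth)
    tree$visit_count[i] <- as.numeric(nd$visits)
    tree$total_reward[i] <- as.numeric(nd$total_reward)
    tree$status[i] <- nd$status
    tree$mols[[i]] <- list(
      string = vapply(nd$molecules, `[[`, character(1), "string"),
      in_stock = vapply(nd$molecules, `[[`, logical(1), "in_stock"),
      transforms = vapply(nd$molecules, function(m) as.integer(m$transforms),
                          integer(1)))
    tree$reaction[i] <- list(
      if (is.null(nd$reaction)) NULL
      else list(template_id = as.integer(nd$reaction$template_id),
                position = as.integer(nd$reaction$position),
                product = nd$reaction$product,
                precursors = unlist(nd$reaction$precursors)))
    if (par > 0L) tree$children[[par]] <- c(tree$children[[par]], i)
  }
  class(tree) <- "search_tree"
  tree
}

#' Write / read a search tree as JSON
#'
#' @param tree a `search_tree`.
#' @param path file path.
#' @return `write_tree` returns `path` invisibly; `read_tree` returns a
#'   `search_tree`.
#' @export
write_tree <- function(tree, path) {
  jsonlite::write_json(export_tree(tree), path, auto_unbox = TRUE,
                       digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("failed to parse tree JSON: ", conditionMessage(e)))
  import_tree(doc)
}

#' Read a target molecule list
#'
#' One molecule per line; blank lines and lines starting with `#` are
#' skipped. When a world is supplied, toy targets are validated against its
#' alphabet with line-numbered errors; without a world lines are passed
#' through untouched (e.g. SMILES for an external-chemistry plugin).
#'
#' @param path text file path.
#' @param world optional [toy_world()] to validate against.
#' @return character vector of targets in file order.
#' @export
read_targets <- function(path, world = NULL) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L) stop("no targets in file: ", path)
  targets <- trimws(lines[keep])
  if (!is.null(world)) {
    for (k in seq_along(targets)) {
      if (!all(strsplit(targets[k], "")[[1]] %in% world$alphabet))
        stop(sprintf("line %d: symbol outside the world alphabet in '%s'",
                     keep[k], targets[k]))
    }
  }
  targets
}
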