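# Hand-built world, small enough for every route to be traced on paper:
#   template 1: "ab" -> ("a", "b");  template 2: "bb" -> ("b", "b")
# stock {a, b}. E.g. "abb" has minimal depth 2 (via either template),
# "aab" is unsynthesizable (its only application leaves "aa", a dead end).
fixture_world <- function() {
  toy_world(2,
            list(list(template_id = 1L, pattern = "ab", parts = c("a", "b")),
                 list(template_id = 2L, pattern = "bb", parts = c("b", "b"))),
            stock = c("a", "b"))
}

# Independent route enumerator: depth-limited enumeration of all route
# trees, coded without the memoised recursion the oracle uses.
enum_synth_within <- function(world, s, d) {
  if (s %in% world$stock) return(TRUE)
  if (d == 0L) return(FALSE)
  for (a in apply_templates(world, s)) {
    if (enum_synth_within(world, a$precursors[1], d - 1L) &&
        enum_synth_within(world, a$precursors[2], d - 1L)) return(TRUE)
  }
  FALSE
}

enum_min_depth <- function(world, s, max_d = 7L) {
  for (d in 0:max_d) if (enum_synth_within(world, s, d)) return(d)
  NA_integer_
}

all_strings <- function(alphabet, max_len) {
  unlist(lapply(seq_len(max_len), function(L)
    apply(expand.grid(rep(list(alphabet), L)), 1L,
          paste, collapse = "")))
}

random_targets <- function(world, n, len_range = 2:6, seed = 1L) {
  withr::with_seed(seed, {
    unique(replicate(n, paste(sample(world$alphabet,
                                     sample(len_range, 1L),
                                     replace = TRUE),
                              collapse = "")))
  })
}

# Random labelled tree built through the JSON import path: random parent
# structure; leaves get a single molecule that is in stock with
# probability p_solved, inner nodes keep an expandable molecule.
make_random_tree <- function(n, seed, p_solved = 0.3) {
  withr::with_seed(seed, {
    parent <- c(0L, if (n > 1L) vapply(2:n, function(i)
      sample.int(i - 1L, 1L), integer(1)))
    has_child <- seq_len(n) %in% parent
    level <- integer(n)
    for (i in seq_len(n)[-1L]) level[i] <- level[parent[i]] + 1L
    solved_leaf <- !has_child & stats::runif(n) < p_solved
    nodes <- lapply(seq_len(n), function(i) {
      list(id = i, parent = parent[i], depth = level[i], visits = 0,
           total_reward = 0,
           status = if (solved_leaf[i]) "solved"
                    else if (has_child[i]) "expanded" else "depth_capped",
           molecules = list(list(string = if (solved_leaf[i]) "a" else "ab",
                                 in_stock = solved_leaf[i],
                                 transforms = level[i])),
           reaction = if (i == 1L) NULL
                      else list(template_id = 1L, position = 1L,
                                product = "ab", precursors = c("a", "b")))
    })
    import_tree(list(schema_version = "1.0",
                     config = unclass(planner_config()),
                     world = world_to_list(fixture_world()),
                     nodes = nodes))
  })
}

# Brute-force label oracle: for every node, exhaustively scan all leaves,
# testing subtree membership by walking each leaf's ancestor chain.
brute_force_labels <- function(tree) {
  n <- n_nodes(tree)
  leaf <- lengths(tree$children[seq_len(n)]) == 0L
  solved_leaf <- vapply(seq_len(n), function(i)
    leaf[i] && all(tree$mols[[i]]$in_stock), logical(1))
  anc <- lapply(seq_len(n), function(i) {
    out <- i
    while (tree$parent[i] > 0L) { i <- tree$parent[i]; out <- c(out, i) }
    out
  })
  vapply(seq_len(n), function(i) {
    if (solved_leaf[i]) return("solved")
    reach <- any(vapply(which(solved_leaf), function(l)
      i %in% anc[[l]], logical(1)))
    if (reach) "internal" else "not_solved"
  }, character(1))
}
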