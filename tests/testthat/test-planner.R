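test_that("exploration term and UCB match their closed forms", {
  expect_equal(exploration_term(1, 1), 0)
  expect_equal(exploration_term(1, exp(1)), 1.4 * sqrt(2))
  expect_equal(exploration_term(4, 10), 1.4 * sqrt(2 * log(10) / 4))
  expect_error(exploration_term(0, 1), "visit counts")

  node <- list(total_reward = 0, visit_count = 1)
  parent <- list(visit_count = 1)
  expect_equal(ucb(node, parent), 0)
  node$total_reward <- 0.975
  expect_equal(ucb(node, parent), 0.975)
  node <- list(total_reward = 1.9, visit_count = 2)
  parent <- list(visit_count = 10)
  expect_equal(ucb(node, parent), 0.95 + exploration_term(2, 10))
  expect_error(ucb(list(total_reward = 0, visit_count = 0), parent),
               "unvisited")
})

test_that("reward matches the native and score-replaced formulas", {
  expect_equal(reward_value(M = 1, M_s = 1, m = 4), 0.975)
  expect_equal(reward_value(M = 3, M_s = 3, m = 4), 0.975)
  # stock term vanishes, depth term decays with depth
  expect_lt(reward_value(M = 2, M_s = 0, m = 30), 1e-10)
  expect_equal(reward_value(M = 1, M_s = 1, m = 2, score_fraction = 0.475,
                            sa_score = 1),
               0.475 + 0.475 + 0.05 / (1 + exp(-2)))
  expect_error(reward_value(M = 1, M_s = 1, m = 2, score_fraction = 0.475),
               "sa_score")
  # bounds: reward stays in (0, 1] over random node configurations
  withr::with_seed(5, {
    for (i in 1:200) {
      M <- sample(1:8, 1); Ms <- sample(0:M, 1); m <- sample(0:10, 1)
      cc <- sample(c(0, 0.2375, 0.475, 0.7125), 1)
      r <- reward_value(M, Ms, m, cc, sa_score = if (cc > 0) runif(1))
      expect_gt(r, 0); expect_lte(r, 1)
    }
  })
})

test_that("score-replaced reward reduces bitwise to the native one at c = 0", {
  withr::with_seed(17, {
    for (i in 1:1000) {
      M <- sample(1:8, 1); Ms <- sample(0:M, 1); m <- sample(0:12, 1)
      expect_identical(
        reward_value(M, Ms, m, score_fraction = 0, sa_score = runif(1)),
        reward_value(M, Ms, m))
    }
  })
})

test_that("expansion replaces the product by precursors with bookkeeping", {
  w <- fixture_world()
  cfg <- planner_config()
  tree <- mcts_search("abb", w, planner_config(iteration_limit = 1))
  root <- get_node(tree, 1)
  # root expanded: both templates apply to "abb"
  expect_equal(root$status, "expanded")
  expect_length(root$children, 2L)
  for (k in root$children) {
    ch <- get_node(tree, k)
    expect_length(ch$molecules$string, 2L)  # M grew by 1: 1 product -> 2 precursors
    expect_equal(ch$depth, 1L)
    expect_true(all(ch$molecules$transforms == 1L))
  }
  # child of template 1 is {a, bb}: "a" in stock, "bb" expandable
  c1 <- get_node(tree, root$children[1])
  expect_equal(c1$incoming_reaction$template_id, 1L)
  expect_setequal(c1$molecules$string, c("a", "bb"))
  # a molecule matching no template becomes a dead end
  w2 <- toy_world(2, list(list(template_id = 1L, pattern = "bb",
                               parts = c("b", "b"))), stock = "b")
  tr2 <- mcts_search("aa", w2, planner_config(iteration_limit = 3))
  expect_equal(n_nodes(tr2), 1L)
  expect_equal(tr2$status[1], "dead_end")
  expect_false(route_found(tr2))
})

test_that("rollout is greedy, terminal-stable and depth-capped", {
  w <- fixture_world()
  cfg <- planner_config(max_transforms = 2L, iteration_limit = 1L)
  tree <- mcts_search("abb", w, cfg)
  solved <- which(tree$status == "solved")
  expect_gt(length(solved), 0)
  expect_equal(rollout(tree, solved[1]), solved[1])
  # "abbb" has minimal depth 2 (via "bb" -> {"ab", "bb"}), so it cannot
  # solve under max_transforms 1 and every depth-1 leaf is capped
  expect_equal(oracle_min_depth(w, "abbb")$min_depth, 2L)
  tr <- mcts_search("abbb", w, planner_config(max_transforms = 1L,
                                              iteration_limit = 50L))
  expect_false(route_found(tr))
  capped <- which(tr$status == "depth_capped")
  expect_gt(length(capped), 0)
  expect_equal(rollout(tr, capped[1]), capped[1])
  # with enough depth the planner attains the oracle-minimal depth
  tr3 <- mcts_search("abbb", w, planner_config(max_transforms = 6L,
                                               iteration_limit = 50L))
  expect_true(route_found(tr3))
  expect_equal(min(tr3$depth[tr3$status == "solved"]), 2L)
})

test_that("backpropagation is additive and accounts for every iteration", {
  w <- fixture_world()
  for (iters in c(1L, 7L, 40L)) {
    tr <- mcts_search("abb", w, planner_config(iteration_limit = iters))
    expect_equal(tr$visit_count[1], iters)  # root sees every path
    # each node's visits equal paths through it: parent visits >= child sum
    for (i in seq_len(n_nodes(tr))) {
      kids <- tr$children[[i]]
      if (length(kids) > 0)
        expect_gte(tr$visit_count[i], sum(tr$visit_count[kids]))
    }
    expect_true(all(tr$total_reward <= tr$visit_count))
  }
  tr <- mcts_search("abb", w, planner_config(iteration_limit = 1))
  before_v <- tr$visit_count[1]; before_q <- tr$total_reward[1]
  backpropagate(tr, 1L, 0.5)
  backpropagate(tr, 1L, 1.0)
  expect_equal(tr$visit_count[1], before_v + 2)
  expect_equal(tr$total_reward[1], before_q + 1.5)
  expect_error(backpropagate(tr, 1L, 1.5), "reward")
})

test_that("select_leaf reproduces an independent argmax re-walk", {
  w <- generate_world(3, 12, 15, 3, seed = 2)
  tr <- mcts_search(random_targets(w, 5, 4:5, seed = 3)[1], w,
                    planner_config(iteration_limit = 60))
  id <- 1L
  while (tr$status[id] == "expanded") {
    kids <- tr$children[[id]]
    vis <- tr$visit_count[kids]
    id <- if (any(vis == 0)) kids[which(vis == 0)[1]] else {
      vals <- vapply(kids, function(k)
        ucb(get_node(tr, k), get_node(tr, id)), numeric(1))
      kids[which.max(vals)]
    }
  }
  expect_identical(select_leaf(tr), id)
})

test_that("search solves in-stock targets trivially and is deterministic", {
  w <- fixture_world()
  tr <- mcts_search("a", w, planner_config(iteration_limit = 10))
  expect_equal(n_nodes(tr), 1L)
  expect_true(route_found(tr))
  expect_equal(classify_nodes(tr), "solved")

  w2 <- generate_world(4, 15, 20, 3, seed = 4)
  tg <- random_targets(w2, 3, 4:5, seed = 8)[1]
  t1 <- mcts_search(tg, w2, planner_config(iteration_limit = 80))
  t2 <- mcts_search(tg, w2, planner_config(iteration_limit = 80))
  expect_identical(export_tree(t1), export_tree(t2))
})

test_that("search is sound and recovers oracle-synthesizable targets", {
  w <- generate_world(4, 20, 30, 3, seed = 5)
  targets <- random_targets(w, 60, 2:6, seed = 6)
  memo <- new.env(parent = emptyenv())
  cfg <- planner_config(iteration_limit = 200, stop_on_solve = TRUE)
  for (tg in targets) {
    res <- oracle_min_depth(w, tg, max_depth = 6, memo = memo)
    found <- route_found(mcts_search(tg, w, cfg))
    if (res$unsynthesizable) expect_false(found, info = tg)
  }
  syn <- Filter(function(tg)
    oracle_min_depth(w, tg, max_depth = 6, memo = memo)$within_limit, targets)
  found <- vapply(syn, function(tg)
    route_found(mcts_search(tg, w, cfg)), logical(1))
  expect_gte(mean(found), 0.95)
})
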