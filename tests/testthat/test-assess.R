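test_that("ROC handles separation, ties and the 4-pair worked example", {
  r <- roc_curve(rep(1, 5), rep(0, 5))
  expect_equal(r$auc, 1)
  expect_equal(r$accuracy_at_best, 1)
  expect_equal(r$best_threshold, 1)

  r2 <- roc_curve(rep(0.5, 4), rep(0.5, 4))
  expect_equal(r2$auc, 0.5)

  # brute force over the 4 pos-neg pairs: wins {0.9>0.7, 0.9>0.85, 0.8>0.7},
  # losses {0.8<0.85} -> AUC 3/4
  r3 <- roc_curve(c(0.9, 0.8), c(0.7, 0.85))
  expect_equal(r3$auc, 0.75)

  expect_equal(r3$fpr[1], 0); expect_equal(r3$tpr[1], 0)
  expect_equal(r3$fpr[length(r3$fpr)], 1)
  expect_equal(r3$tpr[length(r3$tpr)], 1)
  expect_true(all(diff(r3$tpr) >= 0) && all(diff(r3$fpr) >= 0))
  expect_error(roc_curve(numeric(0), 1), "non-empty")
})

test_that("Youden threshold breaks ties toward the higher threshold", {
  # pos {0.3, 0.9}, neg {0.1, 0.7}: J = 0.5 at thresholds 0.9 and 0.3
  r <- roc_curve(c(0.3, 0.9), c(0.1, 0.7))
  expect_equal(r$best_threshold, 0.9)
  expect_equal(r$accuracy_at_best, 0.75)
  # and a clean unique optimum
  r2 <- roc_curve(c(0.6, 0.9), c(0.1, 0.4))
  expect_equal(r2$best_threshold, 0.6)
  expect_equal(r2$accuracy_at_best, 1)
})

test_that("trapezoid and pairwise AUC agree everywhere, including heavy ties", {
  expect_equal(auc_pairwise(0.5, 0.5), 0.5)
  expect_equal(auc_pairwise(c(0.9, 0.8), c(0.7, 0.85)), 0.75)
  withr::with_seed(7, {
    for (i in 1:60) {
      np <- sample(3:60, 1); nn <- sample(3:60, 1)
      # coarse grid forces many ties
      pos <- sample(seq(0, 1, 0.1), np, replace = TRUE)
      neg <- sample(seq(0, 1, 0.1), nn, replace = TRUE)
      expect_lt(abs(roc_curve(pos, neg)$auc - auc_pairwise(pos, neg)), 1e-12)
    }
  })
})

test_that("AUC agrees with pROC on random panels", {
  withr::with_seed(8, {
    for (i in 1:10) {
      pos <- round(runif(40), 2); neg <- round(runif(40, 0, 0.9), 2)
      ref <- as.numeric(pROC::auc(pROC::roc(
        response = c(rep(1, 40), rep(0, 40)), predictor = c(pos, neg),
        direction = "<", quiet = TRUE)))
      expect_equal(auc_pairwise(pos, neg), ref, tolerance = 1e-10)
    }
  })
})

test_that("Spearman correlation matches hand ranks and cor.test", {
  expect_equal(spearman_corr(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_corr(1:10, -(1:10))$rho, -1)
  # hand mid-rank computation: d^2 = (4,1,1,4,0), rho = 1 - 60/120 = 0.5
  res <- spearman_corr(1:5, c(3, 1, 4, 2, 5))
  expect_equal(res$rho, 0.5)
  ref <- suppressWarnings(stats::cor.test(1:5, c(3, 1, 4, 2, 5),
                                          method = "spearman"))
  expect_equal(res$rho, unname(ref$estimate))
  # monotone-transform invariance
  withr::with_seed(9, {
    x <- runif(30); y <- runif(30)
    a <- spearman_corr(x, y)
    b <- spearman_corr(exp(3 * x), y^3 + y)
    expect_equal(a$rho, b$rho)
    expect_equal(a$p_value, b$p_value)
  })
  # t-approximation p matches the closed form
  x <- c(1, 4, 2, 8, 5, 7, 3, 6)
  y <- c(2, 3, 1, 7, 8, 5, 4, 6)
  res2 <- spearman_corr(x, y)
  tt <- res2$rho * sqrt((8 - 2) / (1 - res2$rho^2))
  expect_equal(res2$p_value, 2 * stats::pt(-abs(tt), 6))
  # exact option agrees with cor.test's exact null for small untied samples
  res3 <- spearman_corr(x, y, exact = TRUE)
  expect_equal(res3$p_value,
               stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
  expect_error(spearman_corr(1:3, 3:1), "at least 4")
})

test_that("one-sided paired t-test matches manual formula and t.test", {
  d0 <- c(-0.2, -0.1, 0.1, 0.2)
  res <- paired_one_sided_t(d0)
  expect_equal(res$t_stat, 0)
  expect_equal(res$p_one_sided, 0.5)

  d <- c(0.1, 0.3, -0.1, 0.2)
  res2 <- paired_one_sided_t(d)
  expect_equal(res2$mean_diff, 0.125)
  expect_equal(res2$t_stat, mean(d) / (sd(d) / 2))
  ref <- stats::t.test(d, alternative = "greater")
  expect_equal(res2$t_stat, unname(ref$statistic))
  expect_equal(res2$p_one_sided, ref$p.value)

  expect_error(paired_one_sided_t(rep(1, 5)), "zero variance")
  expect_error(paired_one_sided_t(0.3), "at least 2")
  # p decreases monotonically as all differences shift upward
  withr::with_seed(10, {
    base <- rnorm(20, 0, 0.2)
    ps <- vapply(seq(0, 0.5, 0.1), function(sh)
      paired_one_sided_t(base + sh)$p_one_sided, numeric(1))
    expect_true(all(diff(ps) < 0))
  })
})

test_that("precision and sensitivity reproduce the worked route counts", {
  res <- precision_sensitivity(22, 20, 44)
  expect_equal(round(res$precision, 2), 0.91)
  expect_equal(round(res$sensitivity, 2), 0.45)
  expect_equal(precision_sensitivity(7, 7, 7), list(precision = 1, sensitivity = 1))
  expect_equal(precision_sensitivity(10, 0, 5)$precision, 0)
  expect_error(precision_sensitivity(0, 0, 5), "denominator")
  expect_error(precision_sensitivity(5, 6, 5), "n_found_known")
})

test_that("discrimination report separates signal from noise and handles empties", {
  w <- generate_world(4, 20, 30, 3, seed = 7)
  trees <- lapply(random_targets(w, 25, 3:5, seed = 12)[1:20], function(tg)
    mcts_search(tg, w, planner_config(iteration_limit = 80)))
  rep <- discrimination_report(trees, score_names = c("oracle", "noise"),
                               statistics = c("min", "mean"))
  expect_equal(nrow(rep), 2 * 2 * 2)
  ivn <- rep[rep$comparison == "internal_vs_not_solved", ]
  expect_gt(ivn$auc[ivn$score == "oracle" & ivn$statistic == "min"], 0.85)
  expect_lt(abs(ivn$auc[ivn$score == "noise" & ivn$statistic == "mean"] - 0.5),
            0.15)
  # solved always outscores not_solved under the oracle
  svn <- rep[rep$comparison == "solved_vs_not_solved" & rep$score == "oracle", ]
  expect_true(all(svn$auc[svn$statistic %in% c("min", "mean")] > 0.9))

  # trees with no solved leaf contribute nothing to solved-vs-not_solved
  w2 <- fixture_world()
  dead <- list(mcts_search("aab", w2, planner_config(iteration_limit = 10)))
  rep2 <- discrimination_report(dead, score_names = "oracle",
                                statistics = "mean")
  expect_true(is.na(rep2$auc[rep2$comparison == "solved_vs_not_solved"]))
  expect_equal(rep2$n_pos[rep2$comparison == "solved_vs_not_solved"], 0L)
})
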