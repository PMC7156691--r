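test_that("split_edges removes round(fraction * m) edges reproducibly", {
  g100 <- random_graph(30, 100, 1)
  sp <- split_edges(g100, 0.1, seed = 9)
  expect_equal(nrow(sp$test), 10)
  expect_equal(igraph::ecount(sp$train), 90)

  g152 <- random_graph(40, 152, 2)
  expect_equal(nrow(split_edges(g152, 0.1, seed = 9)$test), 15)

  expect_identical(split_edges(g100, 0.1, seed = 4)$test,
                   split_edges(g100, 0.1, seed = 4)$test)
  expect_false(identical(split_edges(g100, 0.1, seed = 4)$test,
                         split_edges(g100, 0.1, seed = 5)$test))

  # partition invariants: disjoint, union is the original edge set; all
  # nodes survive removal
  e <- network_edges(g100)
  tr <- network_edges(sp$train)
  expect_equal(nrow(tr) + nrow(sp$test), nrow(e))
  expect_setequal(c(paste(tr$i, tr$j), paste(sp$test$i, sp$test$j)),
                  paste(e$i, e$j))
  expect_equal(igraph::vcount(sp$train), igraph::vcount(g100))

  expect_error(split_edges(g100, 0), "fraction")
  expect_error(split_edges(g100, 1), "fraction")
})

test_that("top_precision counts positives in the top k", {
  cand <- data.frame(i = rep("a", 4), j = c("b", "c", "d", "e"))
  tbl <- score_table(cand, c(0.9, 0.5, 0.4, 0.1))
  expect_equal(top_precision(tbl, data.frame(i = "a", j = "b"), k = 1), 1)
  expect_equal(top_precision(tbl, data.frame(i = "a", j = "b")), 1)
  pos2 <- data.frame(i = c("a", "a"), j = c("b", "e"))
  expect_equal(top_precision(tbl, pos2), 0.5)
  expect_error(top_precision(tbl, pos2, k = 10), "number of candidates")
  expect_error(top_precision(tbl, data.frame(i = "q", j = "r")),
               "among the scored")
})

test_that("AUROC is the tie-aware probability of correct ordering", {
  cand <- data.frame(i = rep("a", 3), j = c("b", "c", "d"))
  expect_equal(auroc(score_table(cand, c(0.9, 0.1, 0.2)),
                     data.frame(i = "a", j = "b")), 1)
  expect_equal(auroc(score_table(cand, c(0.3, 0.3, 0.3)),
                     data.frame(i = "a", j = "b")), 0.5)
  cand4 <- data.frame(i = rep("a", 4), j = c("b", "c", "d", "e"))
  tbl <- score_table(cand4, c(0.5, 0.8, 0.6, 0.1))
  expect_equal(auroc(tbl, data.frame(i = c("a", "a"), j = c("b", "c"))), 0.75)
  expect_error(auroc(tbl, data.frame(i = character(), j = character())),
               "at least one")
})

test_that("AUPR is average precision over the positives' ranks", {
  cand <- data.frame(i = rep("a", 4), j = c("b", "c", "d", "e"))
  tbl <- score_table(cand, c(1, 0.8, 0.6, 0.4))
  expect_equal(aupr(tbl, data.frame(i = "a", j = "b")), 1)
  expect_equal(aupr(tbl, data.frame(i = "a", j = "e")), 1 / 4)
  expect_equal(aupr(tbl, data.frame(i = c("a", "a"), j = c("b", "d"))),
               (1 + 2 / 3) / 2)
})

test_that("relative top-precision normalises by the random-ranker expectation", {
  expect_equal(relative_top_precision(10 / 1000, 10, 1000), 1)
  expect_equal(relative_top_precision(0.3, 10, 1000), 30)
  expect_equal(relative_top_precision(0, 10, 1000), 0)
  expect_error(relative_top_precision(0.1, 0, 100), "positive")
})

test_that("metrics hit their extremes for a perfect oracle and behave at random", {
  g <- random_graph(25, 80, 11)
  sp <- split_edges(g, 0.1, seed = 11)
  cand <- all_candidates(sp$train)
  tbl <- oracle_table(cand, sp$test)
  expect_equal(top_precision(tbl, sp$test), 1)
  expect_equal(auroc(tbl, sp$test), 1)
  expect_equal(aupr(tbl, sp$test), 1)

  # uniform random scores: AUROC ~ 0.5, TPR ~ k/N within 3 standard errors
  reps <- 200
  k <- nrow(sp$test)
  N <- nrow(cand)
  stats <- withr::with_seed(42, vapply(seq_len(reps), function(r) {
    tb <- score_table(cand, stats::runif(N), tie_seed = r)
    c(top_precision(tb, sp$test), auroc(tb, sp$test))
  }, numeric(2)))
  se_tpr <- stats::sd(stats[1, ]) / sqrt(reps)
  se_auc <- stats::sd(stats[2, ]) / sqrt(reps)
  expect_lt(abs(mean(stats[1, ]) - k / N), 3 * se_tpr)
  expect_lt(abs(mean(stats[2, ]) - 0.5), 3 * se_auc)

  # all candidates tied at score zero: TPR is driven by the tie shuffle
  tied <- withr::with_seed(43, vapply(seq_len(reps), function(r) {
    top_precision(score_table(cand, numeric(N), tie_seed = r), sp$test)
  }, numeric(1)))
  expect_lt(abs(mean(tied) - k / N), 3 * stats::sd(tied) / sqrt(reps))
})

test_that("significant scores and ranks follow the pairwise t-test procedure", {
  # three identical algorithms: full tie
  x <- cbind(A = c(1, 2, 3), B = c(1, 2, 3), C = c(1, 2, 3))
  r <- network_significant_scores(x)
  expect_equal(unname(r$scores), c(0, 0, 0))
  expect_equal(unname(r$ranks), c(2, 2, 2))
  # A beats B (constant margin) and C (significant t-test); B vs C tied
  y <- cbind(A = c(5, 6, 7, 8), B = c(1, 2, 3, 4), C = c(2, 1, 4, 3))
  ry <- network_significant_scores(y, p = 0.05)
  expect_equal(ry$pairwise, -t(ry$pairwise)) # antisymmetric
  expect_equal(unname(ry$scores), c(2, -1, -1))
  expect_equal(unname(ry$ranks), c(1, 2.5, 2.5))
  expect_equal(sum(ry$ranks), 3 * 4 / 2)

  # two algorithms, one clearly better
  z <- cbind(A = c(5, 6, 7, 8, 9), B = c(1, 2, 3, 4, 3))
  expect_equal(unname(network_significant_scores(z)$ranks), c(1, 2))

  expect_error(network_significant_scores(x[1, , drop = FALSE]), ">= 2")
})

test_that("average significant rank is the column mean", {
  expect_equal(unname(average_significant_rank(rbind(c(1, 2), c(2, 1)))),
               c(1.5, 1.5))
  expect_equal(unname(average_significant_rank(rbind(c(1, 2, 3), c(1, 2, 3)))),
               c(1, 2, 3))
  expect_equal(unname(average_significant_rank(rbind(c(1, 2.5, 2.5)))),
               c(1, 2.5, 2.5))
})

test_that("pairwise MWW/BY comparison flags only real separations", {
  same <- cbind(A = rep(c(1, 2), 5), B = rep(c(1, 2), 5))
  r <- pairwise_method_comparison(same)
  expect_true(all(r$direction == ""))

  sep <- cbind(A = rep(1, 10), B = rep(2, 10))
  r2 <- pairwise_method_comparison(sep)
  expect_equal(r2$direction["A", "B"], "<")
  expect_equal(r2$direction["B", "A"], ">")
  expect_lt(r2$p_adjusted["A", "B"], 0.05)

  # BY-adjusted p-values never fall below the raw one-tailed p
  x <- withr::with_seed(7, matrix(stats::runif(40), 10, 4,
                                  dimnames = list(NULL, LETTERS[1:4])))
  r3 <- pairwise_method_comparison(x)
  for (a in 1:3) {
    for (b in (a + 1):4) {
      alt <- if (mean(x[, a]) <= mean(x[, b])) "less" else "greater"
      raw <- stats::wilcox.test(x[, a], x[, b], alternative = alt,
                                exact = FALSE)$p.value
      expect_gte(r3$p_adjusted[a, b], raw - 1e-12)
    }
  }
  expect_error(pairwise_method_comparison(sep[1, , drop = FALSE]), "networks")
})

test_that("temporal snapshot couples enumerate earlier-later pairs", {
  tp <- temporal_pairs(c("t1", "t2", "t3"))
  expect_equal(tp$earlier, c("t1", "t1", "t2"))
  expect_equal(tp$later, c("t2", "t3", "t3"))
  expect_equal(nrow(temporal_pairs(seq_len(10))), 45)
  expect_equal(nrow(temporal_pairs(character(0))), 0)
})
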