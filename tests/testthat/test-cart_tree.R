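test_that("gini impurity and split impurity evaluate the formulas", {
  expect_equal(gini_impurity(c(10, 0)), 0)
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  expect_equal(gini_impurity(c(3, 1)), 0.375)
  expect_error(gini_impurity(c(0, 0)), "empty node")

  expect_equal(gini_split(c(4, 0), c(1, 3)), 0.1875)
  expect_equal(gini_split(c(2, 2), c(2, 2)), 0.5)
  expect_equal(gini_split(c(1, 0), c(0, 1)), 0)
  expect_error(gini_split(c(0, 0), c(1, 1)), "nonempty")

  # bounds: impurity in [0, 1 - 1/c]
  set.seed(2)
  for (i in 1:50) {
    c_ <- sample(2:4, 1)
    counts <- rmultinom(1, sample(1:20, 1), rep(1 / c_, c_))[, 1]
    if (sum(counts) == 0) next
    g <- gini_impurity(counts)
    expect_gte(g, 0)
    expect_lte(g, 1 - 1 / c_)
  }
})

test_that("best_split separates, breaks ties low, and rejects constants", {
  # perfect separator at the midpoint
  x <- matrix(c(0, 0, 2, 2), 4, 1)
  sp <- best_split(x, c("A", "A", "B", "B"), 1)
  expect_equal(sp$feature, 1L)
  expect_equal(sp$threshold, 1.0)
  expect_equal(sp$gini, 0)

  # two perfect features: lower index wins
  x2 <- cbind(c(0, 0, 2, 2), c(0, 0, 2, 2))
  sp2 <- best_split(x2, c("A", "A", "B", "B"), c(2, 1))
  expect_equal(sp2$feature, 1L)

  # all-constant candidates: no valid split
  expect_null(best_split(matrix(1, 4, 2), c("A", "A", "B", "B"), 1:2))
})

test_that("best_split agrees with the exhaustive oracle on random nodes", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    m <- sample(1:4, 1)
    x <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
    y <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- setdiff(c("A", "B"), y[2])
    cand <- sort(sample(seq_len(m), sample(seq_len(m), 1)))
    got <- best_split(x, y, cand)
    want <- oracle_best_split(x, y, cand)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$feature, want$feature)
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$gini, want$gini, tolerance = 1e-12)
    }
  }
})

test_that("tree growth obeys the stopping rules", {
  x <- matrix(c(0, 0, 1, 2, 2, 2), 6, 1)
  y <- c("A", "A", "A", "B", "B", "B")
  s <- uniform_sampler(1, 1)

  # n_min = N: a single leaf predicting the majority class
  t1 <- grow_tree(x, y, s, n_min = 6)
  expect_equal(t1$nodes$feature, -1L)
  expect_equal(sum(t1$importance), 0)

  # pure labels: single leaf regardless of n_min
  t2 <- grow_tree(x, rep("A", 6), s, n_min = 1)
  expect_equal(length(t2$nodes$feature), 1L)

  # separable data grown to purity reproduces the training labels
  t3 <- grow_tree(x, y, s, n_min = 1)
  expect_equal(as.character(predict_tree(t3, x)), y)
  expect_true(all(t3$nodes$decrease >= 0))
})

test_that("prediction routes threshold-equal values left", {
  # split at 1.0: a sample with value exactly 1 must follow the left child
  x <- matrix(c(0, 0, 2, 2), 4, 1)
  tr <- grow_tree(x, c("A", "A", "B", "B"), uniform_sampler(1, 1), n_min = 1)
  expect_equal(tr$nodes$threshold[1], 1.0)
  expect_equal(as.character(predict_tree(tr, matrix(1, 1, 1))), "A")
  expect_error(predict_tree(tr, matrix(0, 1, 2)), "feature columns")
})

test_that("leaf majority ties go to the earliest canonical label", {
  x <- matrix(c(0, 0), 2, 1)
  tr <- grow_tree(x, c("b", "a"), uniform_sampler(1, 1), n_min = 2)
  expect_equal(as.character(predict_tree(tr, matrix(0, 1, 1))), "a")
})

test_that("recorded decreases are nonnegative on random grown trees", {
  set.seed(21)
  for (i in 1:10) {
    d <- random_dataset(n = 20, m = 5)
    tr <- grow_tree(d$values, d$labels, uniform_sampler(1:5, 3),
                    n_min = 1, seed = i)
    expect_true(all(tr$nodes$decrease >= 0))
    internal <- tr$nodes$feature >= 0
    # strictly decreasing sample counts along every edge
    expect_true(all(tr$nodes$n_node[tr$nodes$left[internal] + 1] <
                      tr$nodes$n_node[internal]))
    expect_true(all(tr$nodes$n_node[tr$nodes$right[internal] + 1] <
                      tr$nodes$n_node[internal]))
  }
})
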