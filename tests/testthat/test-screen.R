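test_that("shadow extension permutes columns and keeps labels", {
  d <- random_dataset(n = 12, m = 5, seed = 51)
  ext <- make_shadow_extended(d, seed = 3)
  expect_equal(dim(ext), c(12L, 10L))
  expect_equal(ext$labels, d$labels)
  expect_equal(ext$feature_ids[1:5], d$feature_ids)
  expect_equal(ext$feature_ids[6:10], paste0(d$feature_ids, "__shadow"))
  expect_equal(ext$values[, 1:5], d$values)
  for (j in 1:5)
    expect_equal(sort(ext$values[, 5 + j]), sort(d$values[, j]))
  expect_identical(make_shadow_extended(d, seed = 3), ext)
  expect_false(identical(make_shadow_extended(d, seed = 4)$values,
                         ext$values))
})

test_that("importance replicates have the right shape and find signal", {
  # labels a deterministic function of feature 1 among nulls
  set.seed(52)
  n <- 60
  x <- cbind(sample(0:2, n, TRUE), matrix(sample(0:2, n * 99, TRUE), n, 99))
  d <- labeled_dataset(x, ifelse(x[, 1] >= 1, "case", "control"))
  rep <- importance_replicates(d, R = 5, K_screen = 20, mtry_screen = 20,
                               seed = 9)
  expect_equal(dim(rep$real_scores), c(5L, 100L))
  expect_length(rep$shadow_max, 5)
  expect_true(all(rep$real_scores >= 0) && all(rep$shadow_max >= 0))
  expect_gt(mean(rep$real_scores[, 1]), mean(rep$shadow_max))
  rep2 <- importance_replicates(d, R = 5, K_screen = 20, mtry_screen = 20,
                                seed = 9)
  expect_identical(rep, rep2)
})

test_that("one-sided rank-sum p-values match the enumerated examples", {
  expect_equal(wilcoxon_greater_pvalue(c(5, 6, 7), c(1, 2, 3)), 0.05)
  expect_equal(wilcoxon_greater_pvalue(c(1, 4), c(2, 3)), 4 / 6)
  expect_equal(wilcoxon_greater_pvalue(c(10, 20), c(1, 2)), 1 / 6)
  expect_error(wilcoxon_greater_pvalue(numeric(0), 1), "nonempty")
})

test_that("exact rank-sum p-values match full enumeration up to 6+6", {
  set.seed(53)
  for (m in 1:6) for (n in 1:6) {
    repeat {  # tie-free draw
      x <- round(rnorm(m), 6); y <- round(rnorm(n), 6)
      if (!anyDuplicated(c(x, y))) break
    }
    expect_equal(wilcoxon_greater_pvalue(x, y),
                 oracle_wilcoxon_greater(x, y),
                 tolerance = 1e-12, label = sprintf("m=%d n=%d", m, n))
  }
})

test_that("stage 1 keeps boundary features and flags empty survivors", {
  rep <- structure(list(
    real_scores = matrix(c(5, 6, 7, 1, 2, 3), nrow = 3,
                         dimnames = list(NULL, c("hit", "dud"))),
    shadow_max = c(1.5, 2.5, 3.5), R = 3), class = "importance_replicates")
  s1 <- stage1_filter(rep, theta = 0.05)
  # p for "hit" is exactly 0.05: the boundary feature must be retained
  expect_equal(unname(s1$wilcoxon_p["hit"]), 0.05)
  expect_equal(s1$informative, 1L)

  s1b <- stage1_filter(rep, theta = 0.01)
  expect_length(s1b$informative, 0)
})

test_that("chi-squared association matches the closed forms and the oracle", {
  # 2x2 table [[10,0],[0,10]]: N(ad-bc)^2 / row/col products = 20
  x <- rep(c(0, 1), each = 10)
  y <- rep(c("case", "control"), each = 10)
  res <- chi2_association(x, y)
  expect_equal(res$statistic, 20)

  # exact independence
  res2 <- chi2_association(rep(c(0, 1), 10),
                           rep(c("case", "control"), each = 10))
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p.value, 1)

  # constant feature
  res3 <- chi2_association(rep(1, 10), rep(c("case", "control"), 5))
  expect_equal(res3$statistic, 0)
  expect_equal(res3$p.value, 1)

  set.seed(54)
  for (i in 1:100) {
    x <- sample(0:2, 40, replace = TRUE)
    y <- sample(c("case", "control"), 40, replace = TRUE)
    if (length(unique(y)) < 2) next
    got <- chi2_association(x, y)
    tab <- table(x, y)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2) next
    expect_equal(got$statistic, oracle_chi2_statistic(tab),
                 tolerance = 1e-12)
  }
})

test_that("continuous features are discretized to tertiles for chi2 only", {
  set.seed(55)
  x <- c(rnorm(50, 2), rnorm(50, -2))
  y <- rep(c("case", "control"), each = 50)
  res <- chi2_association(x, y, feature_kind = "continuous")
  expect_gt(res$statistic, 20)
  expect_lt(res$p.value, 1e-4)
})

test_that("stage 2 partitions the informative set exactly", {
  set.seed(56)
  d <- random_dataset(n = 40, m = 6)
  # plant a strong feature: labels follow column 1
  d$values[, 1] <- ifelse(d$labels == "case", 2, 0)
  s2 <- stage2_partition(d, informative = c(1L, 3L, 5L), alpha = 0.05)
  expect_setequal(c(s2$strong, s2$weak), c(1L, 3L, 5L))
  expect_length(intersect(s2$strong, s2$weak), 0)
  expect_true(1L %in% s2$strong)
  expect_error(stage2_partition(d, integer(0)), "empty")
})

test_that("subspace sizes follow the proportional-floor rule", {
  expect_equal(subspace_sizes(10, 30, 70), list(mtry_s = 3L, mtry_w = 7L))
  expect_equal(subspace_sizes(10, 30, 0), list(mtry_s = 10L, mtry_w = 0L))
  expect_equal(subspace_sizes(10, 0, 30), list(mtry_s = 0L, mtry_w = 10L))
  expect_equal(subspace_sizes(2, 1, 99), list(mtry_s = 1L, mtry_w = 1L))
  # caps at group sizes
  expect_equal(subspace_sizes(10, 2, 3), list(mtry_s = 2L, mtry_w = 3L))
  expect_error(subspace_sizes(5, 0, 0), "empty")
})

test_that("the stratified sampler always includes strong features", {
  s <- stratified_sampler(strong = 1:5, weak = 6:20, mtry_s = 2, mtry_w = 3)
  set.seed(57)
  counts <- numeric(5)
  for (i in 1:10000) {
    draw <- draw_subspace(s)
    expect_length(draw, 5)
    expect_length(intersect(draw, 1:5), 2)
    expect_length(intersect(draw, 6:20), 3)
    counts[draw[draw <= 5]] <- counts[draw[draw <= 5]] + 1
  }
  # inclusion probability mtry_s / |X_s| = 0.4
  expect_true(all(abs(counts / 10000 - 0.4) < 0.02))

  s2 <- stratified_sampler(strong = 3:7, weak = integer(0),
                           mtry_s = 5, mtry_w = 0)
  expect_setequal(draw_subspace(s2), 3:7)
})

test_that("stage-1 screen is conservative under the null", {
  fracs <- numeric(3)
  for (i in 1:3) {
    tr <- generate_case_control(synthetic_spec(50, 50, 100, 0,
                                               effect_delta = 0,
                                               seed = 600 + i))
    scr <- screen_features(tr$dataset, R = 8, K_screen = 25,
                           theta = 0.05, seed = 700 + i)
    fracs[i] <- length(scr$informative) / 100
  }
  expect_lte(mean(fracs), 0.05 + 0.05)
})
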