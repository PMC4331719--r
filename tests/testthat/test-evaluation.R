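vm_fixture <- function(counts, labels = c("a", "b")) {
  structure(list(counts = matrix(as.integer(counts), ncol = length(labels),
                                 dimnames = list(NULL, labels)),
                 denominator = as.integer(rowSums(counts)),
                 label_order = labels),
            class = "vote_matrix")
}

test_that("vote accuracy applies the strict-majority rule", {
  vm <- vm_fixture(rbind(c(5, 0), c(9, 1)))
  expect_equal(test_accuracy(vm, c("a", "a")), 1)

  # a tie between the true class and another counts as incorrect
  vm2 <- vm_fixture(rbind(c(5, 5)))
  expect_equal(test_accuracy(vm2, "a"), 0)

  vm3 <- vm_fixture(rbind(c(7, 3), c(2, 8)))
  expect_equal(test_accuracy(vm3, c("a", "a")), 0.5)

  # zero-denominator rows are excluded with a message
  vm4 <- vm_fixture(rbind(c(4, 0), c(0, 0)))
  expect_message(acc <- test_accuracy(vm4, c("a", "a")), "excluded")
  expect_equal(acc, 1)
})

test_that("rank-based AUC counts concordant pairs with ties at 1/2", {
  expect_equal(binary_auc(c(0.9, 0.1, 0.8, 0.2), rep(c("p", "n"), 2), "p"), 1)
  expect_equal(binary_auc(rep(0.5, 6), rep(c("p", "n"), 3), "p"), 0.5)
  expect_equal(binary_auc(c(0.9, 0.4, 0.6), c("p", "n", "p"), "p"), 1)
  expect_equal(binary_auc(c(0.4, 0.9, 0.6), c("p", "n", "p"), "p"), 0)
  # one concordant pair, one tied pair
  expect_equal(binary_auc(c(0.7, 0.4, 0.4), c("p", "n", "p"), "p"), 0.75)
  expect_error(binary_auc(1:3, c("p", "p", "p")), "2 classes")
})

test_that("margins are vote-fraction leads of the true class", {
  vm <- vm_fixture(rbind(c(10, 0), c(0, 10), c(6, 4)))
  mr <- margins(vm, c("a", "a", "a"))
  expect_equal(mr, c(1, -1, 0.2))
})

test_that("strength/correlation match direct evaluation on a fixture", {
  # 3 trees, 6 samples, binary labels; NA marks in-bag pairs.
  y <- c("a", "a", "a", "b", "b", "b")
  tp <- rbind(c("a", NA,  "a"),
              c("a", "b", NA),
              c(NA,  "a", "b"),
              c("b", "b", NA),
              c("a", NA,  "b"),
              c(NA,  "b", "b"))
  counts <- rbind(c(2, 0), c(1, 1), c(1, 1), c(0, 2), c(1, 1), c(0, 2))
  vm <- vm_fixture(counts)
  sc <- strength_correlation(vm, y, tp)
  # direct evaluation: margins (1,0,0,1,0,1), s = 1/2, var(mr) = 1/4;
  # every tree has p1 = 3/4, p2 = 1/4, sd_k = sqrt(5)/2;
  # rho = (1/4)/(5/4) = 1/5; c/s^2 = (1/5)/(1/4) = 4/5.
  expect_equal(sc$margins, c(1, 0, 0, 1, 0, 1))
  expect_equal(sc$strength, 0.5)
  expect_equal(sc$correlation, 0.2)
  expect_equal(sc$cs2, 0.8)
})

test_that("degenerate margin patterns give zero correlation", {
  y <- c("a", "a", "b", "b")
  tp <- rbind(c("a", "a"), c("a", "a"), c("b", "b"), c("b", "b"))
  vm <- vm_fixture(rbind(c(2, 0), c(2, 0), c(0, 2), c(0, 2)))
  sc <- strength_correlation(vm, y, tp)
  expect_equal(sc$strength, 1)
  expect_equal(sc$correlation, 0)
  expect_equal(sc$cs2, 0)
})

test_that("oob accuracy equals the positive-margin fraction on real fits", {
  d <- random_dataset(n = 40, m = 10, seed = 71)
  f <- fit_forest(d, K = 60, sampler = uniform_sampler(1:10, 3), seed = 8)
  vm <- votes(f, oob_only = TRUE)
  acc <- suppressMessages(test_accuracy(vm, d$labels))
  mr <- suppressMessages(margins(vm, d$labels))
  expect_equal(acc, mean(mr[!is.na(mr)] > 0))
  dg <- forest_diagnostics(f)
  expect_equal(dg$strength, mean(mr, na.rm = TRUE))
  expect_true(is.na(dg$cs2) || dg$cs2 >= 0)
})

test_that("cross-validation folds partition, stratify and reproduce", {
  tr <- generate_case_control(synthetic_spec(24, 36, 40, 5,
                                             effect_delta = 0.55, seed = 72))
  params <- tsrf_params(R = 6, K = 25, K_screen = 25, mtry_screen = 10,
                        seed = 1)
  res <- kfold_cv(tr$dataset, k = 3, params = params, seed = 5,
                  baseline = TRUE)
  fold <- attr(res, "folds")
  expect_length(fold, 60)
  expect_setequal(unique(fold), 1:3)
  # stratification: per-fold class counts within 1 of n_class / k
  tab <- table(fold, tr$dataset$labels)
  expect_true(all(abs(tab[, "case"] - 8) <= 1))
  expect_true(all(abs(tab[, "control"] - 12) <= 1))
  expect_equal(nrow(res), 6)
  expect_setequal(unique(res$model), c("ts-RF", "RF"))
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))

  res2 <- kfold_cv(tr$dataset, k = 3, params = params, seed = 5,
                   baseline = TRUE)
  attr(res2, "folds") <- attr(res, "folds")
  expect_equal(res2, res)

  expect_error(kfold_cv(tr$dataset, k = 30, params = params, seed = 1),
               "at least k")
})
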