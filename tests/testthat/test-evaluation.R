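test_that("stratified splitting keeps class ratios and is deterministic", {
  y <- factor(rep(c("baseline", "vns"), times = c(60, 40)))
  sp <- stratified_split(y, 0.2, seed = 3)
  expect_length(sp$test, 12 + 8)
  expect_equal(sum(y[sp$test] == "baseline"), 12)
  expect_equal(sum(y[sp$test] == "vns"), 8)
  expect_setequal(c(sp$train, sp$test), seq_along(y))

  y2 <- factor(rep(c("baseline", "vns"), times = c(6, 4)))
  sp2 <- stratified_split(y2, 0.2, seed = 3)
  expect_equal(sum(y2[sp2$test] == "baseline"), 1)
  expect_equal(sum(y2[sp2$test] == "vns"), 1)

  sp3 <- stratified_split(y, 0.2, seed = 3)
  expect_identical(sp, sp3)
  expect_error(stratified_split(factor(c("a", "b", "b"))), ">= 2")
})

test_that("AUC is the Mann-Whitney statistic with tie credit", {
  expect_equal(auc_mann_whitney(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auc_mann_whitney(c(0, 0, 1, 1), c(0.9, 0.8, 0.2, 0.1)), 0)
  withr::with_seed(17, {
    for (i in 1:20) {
      y <- sample(0:1, 20, replace = TRUE)
      if (length(unique(y)) < 2) next
      s <- sample(seq(0, 1, by = 0.1), 20, replace = TRUE)  # forces ties
      expect_equal(auc_mann_whitney(y, s), oracle_auc(y, s),
                   tolerance = 1e-12)
    }
  })
  # invariance under strictly monotone transforms of the scores
  withr::with_seed(18, {
    y <- rep(0:1, each = 15)
    s <- rnorm(30)
    a0 <- auc_mann_whitney(y, s)
    expect_equal(auc_mann_whitney(y, exp(s)), a0)
    expect_equal(auc_mann_whitney(y, 3 * s - 10), a0)
  })
  expect_error(auc_mann_whitney(rep(1, 5), rnorm(5)), "single class")
})

test_that("F-beta metrics match their closed forms and F2 favors recall", {
  # TP = 2, FP = 1, FN = 2: precision 2/3, recall 1/2
  y_true <- c(1, 1, 1, 1, 0, 0)
  y_pred <- c(1, 1, 0, 0, 1, 0)
  m <- compute_metrics(y_true, y_pred, y_pred)
  expect_equal(m$f1, 2 * (2 / 3) * 0.5 / (2 / 3 + 0.5), tolerance = 1e-12)
  expect_equal(m$f2, 0.52632, tolerance = 1e-5)
  expect_equal(m$accuracy, 3 / 6)
  # on a (P, R) grid with R > P, F2 > F1
  for (P in c(0.3, 0.5, 0.7)) {
    for (R in c(P + 0.1, P + 0.2)) {
      f1 <- 2 * P * R / (P + R)
      f2 <- 5 * P * R / (4 * P + R)
      expect_gt(f2, f1)
    }
  }
})

test_that("cross-validation is stratified, unshuffled and well calibrated", {
  # perfectly separable table: every fold AUC is 1
  tab <- make_planted_table(n = 40, p = 4, n_signal = 2, effect = 8,
                            seed = 21)
  cv <- cross_validate("random_forest", tab$X, tab$y, seed = 2)
  expect_equal(cv$fold_auc, rep(1, 5))
  expect_length(cv$fold_accuracy, 5)
  expect_false(is.null(cv$feature_importances))

  # n = 10, k = 5: folds of exactly 2 (one per class)
  tab2 <- make_planted_table(n = 10, p = 3, seed = 22)
  fold <- eggpipe:::.stratified_folds(tab2$y, 5)
  expect_equal(unname(table(fold)), rep(2L, 5), ignore_attr = TRUE)
  expect_true(all(table(fold, tab2$y) == 1))

  # labels independent of features: mean AUC near chance
  withr::with_seed(23, {
    aucs <- vapply(1:6, function(i) {
      X <- as.data.frame(matrix(rnorm(80 * 4), 80, 4))
      y <- factor(rep(c("baseline", "vns"), 40))
      mean(cross_validate("gaussian_nb", X, y, seed = i)$fold_auc)
    }, numeric(1))
    expect_lt(abs(mean(aucs) - 0.5), 0.1)
  })
  expect_error(cross_validate("random_forest", tab2$X,
                              factor(rep(c("a", "b"), c(8, 2))), k = 5),
               "k members")
})

test_that("every classifier family trains and scores", {
  tab <- make_planted_table(n = 40, p = 4, n_signal = 2, effect = 4,
                            seed = 31)
  for (m in classifier_names()) {
    cv <- cross_validate(m, tab$X, tab$y, seed = 4)
    expect_length(cv$fold_auc, 5)
    expect_true(all(cv$fold_auc >= 0 & cv$fold_auc <= 1))
    expect_gt(mean(cv$fold_auc), 0.8)   # strong planted effect
  }
})

test_that("the KS statistic equals the exhaustive ECDF oracle", {
  expect_equal(
    suppressWarnings(stats::ks.test(c(0.9, 1.0), c(0.1, 0.2, 0.3))$statistic),
    1, ignore_attr = TRUE)
  withr::with_seed(41, {
    for (i in 1:25) {
      a <- rnorm(sample(3:30, 1))
      b <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
      expect_equal(
        unname(suppressWarnings(stats::ks.test(a, b)$statistic)),
        oracle_ks_stat(a, b), tolerance = 1e-12)
    }
  })
})

test_that("the permutation KS test separates signal from null", {
  tab <- make_planted_table(n = 50, p = 4, n_signal = 2, effect = 6,
                            seed = 51)
  pt <- permutation_ks_test("random_forest", tab$X, tab$y, n_perm = 30,
                            seed = 7)
  expect_length(pt$observed_aucs, 5)
  expect_length(pt$null_aucs, 150)
  # separable table: observed AUCs all 1, ECDFs (almost) disjoint -- a rare
  # chance-perfect null fold can shave the supremum below 1
  expect_equal(pt$observed_aucs, rep(1, 5))
  expect_gte(pt$ks_statistic, 0.95)
  expect_lt(pt$p_value, 0.01)
  expect_true(pt$reject_at_0.05)
  expect_error(permutation_ks_test("random_forest", tab$X, tab$y,
                                   n_perm = 0), "n_perm")
})

test_that("the permutation test keeps its type-I error under the null", {
  # exercised with the pipeline's own classifier: fold AUCs of a bagged
  # forest are sufficiently decorrelated for the pooled-null KS comparison
  withr::with_seed(61, {
    rejections <- vapply(1:20, function(i) {
      X <- as.data.frame(matrix(rnorm(40 * 3), 40, 3))
      y <- factor(rep(c("baseline", "vns"), 20))
      pt <- permutation_ks_test("random_forest", X, y, n_perm = 30,
                                seed = 100 + i)
      pt$p_value < 0.05
    }, logical(1))
    expect_lte(mean(rejections), 0.10)
  })
})

test_that("feature-set comparison runs all five configurations", {
  tab <- make_planted_table(n = 50, p = 6, n_signal = 2, effect = 6,
                            seed = 71)
  cmp <- compare_feature_sets(tab$X, tab$y,
                              scenario_selected = tab$planted,
                              other_scenario_selected = c("f05", "f06"),
                              n_rep = 20, seed = 3)
  expect_length(cmp$selected, 5)
  expect_length(cmp$random_subsets, 100)
  expect_length(cmp$shuffled_labels, 100)
  expect_equal(cmp$ks_vs_shuffled$statistic, c(D = 1))
  expect_lt(abs(mean(cmp$shuffled_labels) - 0.5), 0.05)
  # selected set = full set: identical to the all-features configuration
  cmp2 <- compare_feature_sets(tab$X, tab$y,
                               scenario_selected = colnames(tab$X),
                               other_scenario_selected = tab$planted,
                               n_rep = 2, seed = 3)
  expect_equal(cmp2$selected, cmp2$all_features)
  expect_error(
    compare_feature_sets(tab$X, tab$y, "not_a_feature", tab$planted),
    "universe")
})

test_that("random-search tuning honors its budget and argmax contracts", {
  tab <- make_planted_table(n = 40, p = 4, n_signal = 1, effect = 2,
                            seed = 81)
  t1 <- tune_best_model("random_forest", tab$X, tab$y, budget = 1, seed = 5)
  expect_length(t1$trajectory, 1)
  expect_equal(t1$cv_auc, t1$default_auc)
  t5 <- tune_best_model("random_forest", tab$X, tab$y, budget = 5, seed = 5)
  expect_gte(t5$cv_auc, t5$default_auc)
  expect_equal(t5$cv_auc, max(t5$trajectory))
  t5b <- tune_best_model("random_forest", tab$X, tab$y, budget = 5, seed = 5)
  expect_identical(t5$trajectory, t5b$trajectory)
  expect_error(tune_best_model("random_forest", tab$X, tab$y, budget = 0),
               "budget")
})
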