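#' @title Classifier training, metrics and permutation significance
#' @description Stratified splitting, unshuffled stratified 5-fold
#'   cross-validation over five classifier families, AUC/accuracy/F1/F2
#'   metrics, the 1000-permutation Kolmogorov-Smirnov significance test, and
#'   the feature-set comparison experiment.
#' @name evaluation
NULL

#' Names of the candidate classifiers
#' @return character vector.
#' @export
classifier_names <- function() {
  c("random_forest", "svm_linear", "svm_rbf", "gaussian_nb",
    "logistic_regression")
}

#' ROC AUC as the Mann-Whitney rank statistic
#'
#' Tied scores receive half credit. Equivalent to the trapezoidal area under
#' the ROC curve.
#'
#' @param y_true 0/1 vector (or two-level factor; the second level is the
#'   positive class).
#' @param y_score numeric scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(y_true, y_score) {
  if (is.factor(y_true)) y_true <- as.integer(y_true == levels(y_true)[2])
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: y_true contains a single class", call. = FALSE)
  r <- rank(y_score)
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics for one fold
#'
#' @param y_true 0/1 vector or two-level factor.
#' @param y_score numeric scores for the AUC.
#' @param y_pred 0/1 predictions for accuracy and F-scores.
#' @return named list: `auc`, `accuracy`, `f1`, `f2`. F-scores are 0 when
#'   precision and recall are both 0.
#' @export
compute_metrics <- function(y_true, y_score, y_pred) {
  if (is.factor(y_true)) y_true <- as.integer(y_true == levels(y_true)[2])
  if (is.factor(y_pred)) y_pred <- as.integer(y_pred == levels(y_pred)[2])
  auc <- auc_mann_whitney(y_true, y_score)
  acc <- mean(y_true == y_pred)
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  fbeta <- function(beta) {
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (prec + rec == 0) return(0)
    (1 + beta^2) * prec * rec / (beta^2 * prec + rec)
  }
  list(auc = auc, accuracy = acc, f1 = fbeta(1), f2 = fbeta(2))
}

#' Stratified train/test split
#'
#' Per-class test counts are `round(test_fraction * class count)`; sampling
#' is seeded and reproducible.
#'
#' @param n either an integer vector of labels/factor, or a feature table
#'   with a `label` column.
#' @param test_fraction fraction held out (default 0.2).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(n, test_fraction = 0.2, seed = 1L) {
  y <- if (is.data.frame(n)) n$label else n
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("need exactly two classes", call. = FALSE)
  if (any(table(y) < 2)) stop("each class needs >= 2 members", call. = FALSE)
  test_idx <- .with_seed(seed, {
    unlist(lapply(levels(y), function(cls) {
      idx <- which(y == cls)
      n_test <- round(test_fraction * length(idx))
      sort(sample(idx, n_test))
    }))
  })
  test_idx <- sort(test_idx)
  list(train = setdiff(seq_along(y), test_idx), test = test_idx)
}

# fit a classifier and return a score function over new data
.fit_classifier <- function(model_name, X, y, seed = 1L, params = list()) {
  pos <- levels(y)[2]
  switch(
    model_name,
    random_forest = {
      set.seed(seed)
      ntree <- if (!is.null(params$ntree)) params$ntree else 100L
      mtry <- if (!is.null(params$mtry)) params$mtry else
        max(1L, floor(sqrt(ncol(X))))
      nodesize <- if (!is.null(params$nodesize)) params$nodesize else 1L
      fit <- randomForest::randomForest(X, y, ntree = ntree, mtry = mtry,
                                        nodesize = nodesize)
      list(score = function(newX)
             stats::predict(fit, newX, type = "prob")[, pos],
           importance = randomForest::importance(fit)[, 1])
    },
    svm_linear = ,
    svm_rbf = {
      kern <- if (model_name == "svm_linear") "linear" else "radial"
      cost <- if (!is.null(params$cost)) params$cost else 1
      fit <- e1071::svm(X, y, kernel = kern, cost = cost,
                        probability = TRUE)
      list(score = function(newX) {
        pr <- stats::predict(fit, newX, probability = TRUE)
        attr(pr, "probabilities")[, pos]
      }, importance = NULL)
    },
    gaussian_nb = {
      fit <- e1071::naiveBayes(X, y)
      list(score = function(newX)
             stats::predict(fit, newX, type = "raw")[, pos],
           importance = NULL)
    },
    logistic_regression = {
      dat <- data.frame(X, .y = y)
      fit <- suppressWarnings(stats::glm(.y ~ ., data = dat,
                                         family = stats::binomial()))
      list(score = function(newX)
             suppressWarnings(stats::predict(fit, newX,
                                             type = "response")),
           importance = NULL)
    },
    stop("unknown model: ", model_name)
  )
}

#' Stratified unshuffled k-fold cross-validation
#'
#' Folds are assigned per class in the original row order (no shuffling);
#' the model is refit on each training fold and scored on the held-out fold.
#'
#' @param model_name one of [classifier_names()].
#' @param X numeric matrix / data.frame of features.
#' @param y two-class factor (second level = positive class).
#' @param k number of folds (default 5).
#' @param seed integer seed (forest refits).
#' @param params optional model hyperparameters (see [tune_best_model()]).
#' @return object of class `egg_cv_result`: `model_name`, `fold_auc`,
#'   `fold_accuracy`, `fold_f1`, `fold_f2`, and `feature_importances`
#'   (fold-averaged; forest models only).
#' @export
cross_validate <- function(model_name, X, y, k = 5L, seed = 1L,
                           params = list()) {
  model_name <- match.arg(model_name, classifier_names())
  X <- as.data.frame(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("need exactly two classes", call. = FALSE)
  if (any(table(y) < k))
    stop("need at least k members per class", call. = FALSE)
  fold <- .stratified_folds(y, k)
  pos <- levels(y)[2]
  metrics <- vector("list", k)
  imp <- NULL
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[!tr])) < 2)
      stop(sprintf("fold %d is degenerate (single class)", f),
           call. = FALSE)
    mdl <- .fit_classifier(model_name, X[tr, , drop = FALSE], y[tr],
                           seed = .sub_seed(seed, f), params = params)
    score <- mdl$score(X[!tr, , drop = FALSE])
    pred <- as.integer(score >= 0.5)
    metrics[[f]] <- compute_metrics(y[!tr], score, pred)
    if (!is.null(mdl$importance)) {
      imp <- if (is.null(imp)) mdl$importance else imp + mdl$importance
    }
  }
  structure(
    list(model_name = model_name,
         fold_auc = vapply(metrics, `[[`, numeric(1), "auc"),
         fold_accuracy = vapply(metrics, `[[`, numeric(1), "accuracy"),
         fold_f1 = vapply(metrics, `[[`, numeric(1), "f1"),
         fold_f2 = vapply(metrics, `[[`, numeric(1), "f2"),
         feature_importances = if (!is.null(imp)) imp / k else NULL),
    class = "egg_cv_result")
}

#' Permutation test of cross-validated AUC with a two-sample KS comparison
#'
#' Computes the observed k-fold AUCs with the true labels, then repeats the
#' cross-validation `n_perm` times with the labels randomly shuffled,
#' pooling all `k * n_perm` null fold AUCs. The observed and null AUC
#' samples are compared with a two-sample Kolmogorov-Smirnov test.
#'
#' @inheritParams cross_validate
#' @param n_perm number of label permutations (default 1000).
#' @return object of class `egg_permutation_test`: `observed_aucs`,
#'   `null_aucs`, `ks_statistic`, `p_value`, `reject_at_0.05`.
#' @export
permutation_ks_test <- function(model_name, X, y, k = 5L, n_perm = 1000L,
                                seed = 1L, params = list()) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  obs <- cross_validate(model_name, X, y, k = k, seed = seed,
                        params = params)$fold_auc
  y <- droplevels(as.factor(y))
  null_aucs <- numeric(0)
  for (p in seq_len(n_perm)) {
    yp <- .with_seed(.sub_seed(seed, 1000L + p), sample(y))
    cv <- cross_validate(model_name, X, yp, k = k,
                         seed = .sub_seed(seed, 2000L + p), params = params)
    null_aucs <- c(null_aucs, cv$fold_auc)
  }
  ks <- suppressWarnings(stats::ks.test(obs, null_aucs))
  structure(
    list(observed_aucs = obs, null_aucs = null_aucs,
         ks_statistic = unname(ks$statistic), p_value = ks$p.value,
         reject_at_0.05 = ks$p.value < 0.05),
    class = "egg_permutation_test")
}

#' @export
print.egg_permutation_test <- function(x, ...) {
  cat(sprintf(
    "<egg_permutation_test> observed mean AUC %.3f vs null mean %.3f; KS = %.3f, p = %.3g\n",
    mean(x$observed_aucs), mean(x$null_aucs), x$ks_statistic, x$p_value))
  invisible(x)
}

#' Compare classifier performance across feature sets
#'
#' Reproduces the feature-set comparison experiment: cross-validated AUCs
#' for (a) this scenario's selected features, (b) the other scenario's
#' selected features, (c) all features, (d) repeated random same-size
#' feature subsets, and (e) repeated label shuffles, plus KS tests of (a)
#' against (d) and (a) against (e).
#'
#' @param X feature matrix / data.frame.
#' @param y two-class factor.
#' @param scenario_selected character vector: this scenario's selected
#'   features.
#' @param other_scenario_selected character vector: the other scenario's
#'   selected features.
#' @param model_name classifier (default random forest).
#' @param n_rep repetitions for the random-subset and shuffled-label cases.
#' @param k folds.
#' @param seed integer seed.
#' @return list of per-configuration fold-AUC vectors (`selected`,
#'   `other_selected`, `all_features`, `random_subsets`, `shuffled_labels`)
#'   and the two KS tests (`ks_vs_random`, `ks_vs_shuffled`).
#' @export
compare_feature_sets <- function(X, y, scenario_selected,
                                 other_scenario_selected,
                                 model_name = "random_forest",
                                 n_rep = 100L, k = 5L, seed = 1L) {
  X <- as.data.frame(X)
  feats <- colnames(X)
  if (length(scenario_selected) == 0 || length(other_scenario_selected) == 0)
    stop("selected feature sets must be non-empty", call. = FALSE)
  if (!all(scenario_selected %in% feats) ||
      !all(other_scenario_selected %in% feats))
    stop("selected features not in the feature universe", call. = FALSE)
  y <- droplevels(as.factor(y))

  auc_a <- cross_validate(model_name, X[, scenario_selected, drop = FALSE],
                          y, k, seed = .sub_seed(seed, 1))$fold_auc
  auc_b <- cross_validate(model_name,
                          X[, other_scenario_selected, drop = FALSE],
                          y, k, seed = .sub_seed(seed, 2))$fold_auc
  auc_c <- cross_validate(model_name, X, y, k,
                          seed = .sub_seed(seed, 3))$fold_auc
  auc_d <- unlist(lapply(seq_len(n_rep), function(i) {
    sub <- .with_seed(.sub_seed(seed, 100L + i),
                      sample(feats, length(scenario_selected)))
    cross_validate(model_name, X[, sub, drop = FALSE], y, k,
                   seed = .sub_seed(seed, 200L + i))$fold_auc
  }))
  auc_e <- unlist(lapply(seq_len(n_rep), function(i) {
    yp <- .with_seed(.sub_seed(seed, 300L + i), sample(y))
    cross_validate(model_name, X[, scenario_selected, drop = FALSE], yp, k,
                   seed = .sub_seed(seed, 400L + i))$fold_auc
  }))
  list(selected = auc_a, other_selected = auc_b, all_features = auc_c,
       random_subsets = auc_d, shuffled_labels = auc_e,
       ks_vs_random = suppressWarnings(stats::ks.test(auc_a, auc_d)),
       ks_vs_shuffled = suppressWarnings(stats::ks.test(auc_a, auc_e)))
}

#' Seeded random-search hyperparameter tuning
#'
#' Draws `budget - 1` random configurations from a documented grid for the
#' given model (the first candidate is always the default configuration) and
#' returns the one with the best mean cross-validated AUC.
#'
#' @inheritParams cross_validate
#' @param budget total number of configurations evaluated (>= 1).
#' @return list with `params`, `cv_auc` (best mean AUC), `default_auc`, and
#'   `trajectory` (per-candidate mean AUCs).
#' @export
tune_best_model <- function(model_name, X, y, budget = 20L, k = 5L,
                            seed = 1L) {
  if (budget < 1) stop("budget must be >= 1", call. = FALSE)
  model_name <- match.arg(model_name, classifier_names())
  draw <- function(i) .with_seed(.sub_seed(seed, 500L + i), switch(
    model_name,
    random_forest = list(ntree = sample(c(100L, 200L, 300L, 500L), 1),
                         mtry = sample(seq_len(max(1L, ncol(as.data.frame(X)))), 1),
                         nodesize = sample(c(1L, 3L, 5L), 1)),
    svm_linear = ,
    svm_rbf = list(cost = 10^stats::runif(1, -2, 2)),
    list()   # no tunables for NB / logistic
  ))
  cands <- c(list(list()), lapply(seq_len(budget - 1L), draw))
  scores <- vapply(seq_along(cands), function(i) {
    mean(cross_validate(model_name, X, y, k = k,
                        seed = .sub_seed(seed, 600L + i),
                        params = cands[[i]])$fold_auc)
  }, numeric(1))
  best <- which.max(scores)
  list(params = cands[[best]], cv_auc = scores[best],
       default_auc = scores[1], trajectory = scores)
}
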