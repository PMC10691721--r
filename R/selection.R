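#' @title Ensemble voting feature selection
#' @description Nine base selectors each produce a nonnegative per-feature
#'   weight vector normalized to sum one; the voting step averages the
#'   vectors, ranks features by averaged weight, and keeps the shortest
#'   descending prefix whose cumulative weight reaches a cutoff (default
#'   0.9). A Spearman-distance hierarchical clustering of the feature
#'   columns serves as a redundancy diagnostic.
#' @name selection
NULL

#' Spearman-distance hierarchical clustering of features
#'
#' Computes the Spearman correlation matrix across feature columns,
#' transforms it to a distance (`1 - rho`), and clusters with average
#' linkage. The leaf order is what a clustered correlation heatmap uses.
#'
#' @param x numeric matrix or data.frame of feature columns (>= 2 features,
#'   >= 3 rows).
#' @return list with `spearman` (correlation matrix), `distance`, `linkage`
#'   (an `hclust` object), and `leaf_order` (feature names in dendrogram
#'   order).
#' @export
spearman_distance_cluster <- function(x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 2, nrow(x) >= 3)
  const <- apply(x, 2, function(col) stats::sd(col) == 0)
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  if (any(const)) {
    warning("constant feature column(s): correlations set to 0")
    rho[const, ] <- 0
    rho[, const] <- 0
  }
  diag(rho) <- 1
  d <- 1 - rho
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  list(spearman = rho, distance = d, linkage = hc,
       leaf_order = colnames(x)[hc$order])
}

#' Names of the base feature-selection methods
#' @return character vector.
#' @export
selector_methods <- function() {
  c("anova_f", "mutual_info", "l1_lsvc", "l2_lsvc", "rfe_rf",
    "sfs_backward", "sfs_forward", "perm_importance_rf",
    "variance_threshold")
}

# ---- helpers -------------------------------------------------------------

# stratified contiguous (unshuffled) k-fold assignment, sklearn-style:
# each class's ordered indices are cut into k consecutive chunks
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    sizes <- rep(length(idx) %/% k, k)
    extra <- length(idx) %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    fold[idx] <- rep(seq_len(k), times = sizes)
  }
  fold
}

.zscore_train <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(test, 2, mu), 2, sdv, "/"))
}

# equal-frequency binned mutual information between a numeric feature and a
# discrete label (nats)
.binned_mi <- function(x, y, n_bins = 10L) {
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(qs) < 2) return(0)
  bx <- cut(x, breaks = qs, include.lowest = TRUE)
  tab <- table(bx, y)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  }
  max(mi, 0)
}

.train_auc_glm <- function(X, y01) {
  dat <- data.frame(X, .y = y01)
  fit <- suppressWarnings(stats::glm(.y ~ ., data = dat,
                                     family = stats::binomial()))
  auc_mann_whitney(y01, suppressWarnings(stats::predict(fit, type = "response")))
}

# greedy sequential feature selection maximizing in-sample logistic AUC
.sfs <- function(X, y01, k_target, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  p <- ncol(X)
  feats <- colnames(X)
  if (direction == "forward") {
    sel <- character(0)
    while (length(sel) < k_target) {
      cand <- setdiff(feats, sel)
      scores <- vapply(cand, function(f)
        .train_auc_glm(X[, c(sel, f), drop = FALSE], y01), numeric(1))
      sel <- c(sel, cand[which.max(scores)])
    }
    sel
  } else {
    sel <- feats
    while (length(sel) > k_target) {
      scores <- vapply(sel, function(f)
        .train_auc_glm(X[, setdiff(sel, f), drop = FALSE], y01), numeric(1))
      sel <- setdiff(sel, sel[which.max(scores)])   # drop least harmful
    }
    sel
  }
}

# single-fold raw importance vector for one method (named, >= 0 after clip)
.fold_importance <- function(method, X_tr, y_tr, X_te, y_te, k_target,
                             n_tree, seed) {
  feats <- colnames(X_tr)
  y01 <- as.integer(y_tr == levels(y_tr)[2])
  imp <- switch(
    method,
    anova_f = vapply(feats, function(f) {
      stats::oneway.test(X_tr[, f] ~ y_tr, var.equal = TRUE)$statistic
    }, numeric(1)),
    mutual_info = vapply(feats, function(f) .binned_mi(X_tr[, f], y_tr),
                         numeric(1)),
    l1_lsvc = {
      z <- .zscore_train(X_tr, X_te)
      fit <- glmnet::glmnet(as.matrix(z$train), y_tr,
                            family = "binomial", alpha = 1,
                            lambda = 0.01, standardize = FALSE,
                            thresh = 1e-12)
      abs(as.numeric(fit$beta))
    },
    l2_lsvc = {
      z <- .zscore_train(X_tr, X_te)
      fit <- e1071::svm(as.matrix(z$train), y_tr, kernel = "linear",
                        scale = FALSE)
      abs(as.numeric(t(fit$coefs) %*% fit$SV))
    },
    rfe_rf = {
      # recursive elimination to k_target survivors; weight 1/rank where
      # rank 1 = best survivor and first-eliminated features rank last
      remaining <- feats
      elim <- character(0)
      set.seed(seed)
      while (length(remaining) > k_target) {
        rf <- randomForest::randomForest(X_tr[, remaining, drop = FALSE],
                                         y_tr, ntree = n_tree)
        im <- randomForest::importance(rf)[, 1]
        worst <- remaining[which.min(im)]
        elim <- c(elim, worst)
        remaining <- setdiff(remaining, worst)
      }
      rf <- randomForest::randomForest(X_tr[, remaining, drop = FALSE],
                                       y_tr, ntree = n_tree)
      im <- randomForest::importance(rf)[, 1]
      ranked <- c(remaining[order(im, decreasing = TRUE)], rev(elim))
      w <- stats::setNames(1 / seq_along(ranked), ranked)
      w[feats]
    },
    sfs_backward = ,
    sfs_forward = {
      z <- .zscore_train(X_tr, X_te)
      dirn <- if (method == "sfs_forward") "forward" else "backward"
      sel <- .sfs(z$train, y01, k_target, dirn)
      stats::setNames(as.numeric(feats %in% sel) / length(sel), feats)
    },
    perm_importance_rf = {
      set.seed(seed)
      rf <- randomForest::randomForest(X_tr, y_tr, ntree = n_tree)
      base_auc <- auc_mann_whitney(
        as.integer(y_te == levels(y_te)[2]),
        stats::predict(rf, X_te, type = "prob")[, 2])
      vapply(feats, function(f) {
        drops <- vapply(1:5, function(rep) {
          Xp <- X_te
          Xp[, f] <- sample(Xp[, f])
          base_auc - auc_mann_whitney(
            as.integer(y_te == levels(y_te)[2]),
            stats::predict(rf, Xp, type = "prob")[, 2])
        }, numeric(1))
        mean(drops)
      }, numeric(1))
    },
    stop("unknown selector method: ", method)
  )
  imp <- stats::setNames(as.numeric(imp), feats)
  imp[!is.finite(imp)] <- 0
  pmax(imp, 0)
}

#' Run one base feature selector
#'
#' Importance-bearing methods run under stratified unshuffled 5-fold
#' cross-validation: per-fold importance vectors are averaged, clipped at
#' zero, then normalized to sum one. `variance_threshold` runs once on all
#' data and assigns `1/k` to each of the `k` surviving features. Subset-only
#' methods (forward/backward sequential selection) likewise spread `1/k`
#' over their selected `k = ceiling(p/2)` features; recursive feature
#' elimination weights features by inverse elimination rank.
#'
#' @param method one of [selector_methods()].
#' @param X numeric matrix / data.frame of features (no missing values).
#' @param y two-class factor (or coercible) of window labels.
#' @param cv_folds number of folds (default 5).
#' @param k_target subset size for RFE/SFS (default `ceiling(p / 2)`).
#' @param n_tree trees for the forest-based selectors (default 100).
#' @param var_threshold variance cutoff for `variance_threshold` (default 0:
#'   only zero-variance features are dropped).
#' @param seed integer seed for the stochastic selectors.
#' @return object of class `egg_selector_weights`: list with `method_name`
#'   and `weights` (named, nonnegative, summing to one).
#' @export
run_selector <- function(method, X, y, cv_folds = 5L,
                         k_target = NULL, n_tree = 100L,
                         var_threshold = 0, seed = 1L) {
  method <- match.arg(method, selector_methods())
  X <- as.data.frame(X)
  stopifnot(!anyNA(X))
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("need exactly two classes", call. = FALSE)
  feats <- colnames(X)
  p <- length(feats)
  if (is.null(k_target)) k_target <- ceiling(p / 2)

  if (method == "variance_threshold") {
    v <- apply(X, 2, stats::var)
    keep <- feats[v > var_threshold]
    if (length(keep) == 0) stop("variance threshold removed every feature",
                                call. = FALSE)
    w <- stats::setNames(rep(0, p), feats)
    w[keep] <- 1 / length(keep)
    return(structure(list(method_name = method, weights = w),
                     class = "egg_selector_weights"))
  }

  fold <- .stratified_folds(y, cv_folds)
  for (f in seq_len(cv_folds)) {
    if (length(unique(y[fold != f])) < 2 ||
        length(unique(y[fold == f])) < 2 ||
        any(table(y[fold != f]) < 2))
      stop(sprintf("fold %d is degenerate (single class)", f), call. = FALSE)
  }
  acc <- stats::setNames(rep(0, p), feats)
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    acc <- acc + .fold_importance(method, X[tr, , drop = FALSE], y[tr],
                                  X[!tr, , drop = FALSE], y[!tr],
                                  k_target, n_tree,
                                  seed = .sub_seed(seed, f))
  }
  w <- acc / cv_folds
  tot <- sum(w)
  if (tot == 0) w[] <- 1 / p else w <- w / tot
  structure(list(method_name = method, weights = w),
            class = "egg_selector_weights")
}

#' Average selector weights and pick the cumulative-0.9 subset
#'
#' Arithmetic mean of the per-method weight vectors (features missing from a
#' method count as 0), re-normalized to sum one, sorted in descending order
#' (ties broken alphabetically by feature name). The selected subset is the
#' shortest prefix whose cumulative averaged weight reaches `cutoff`,
#' including the crossing feature.
#'
#' @param all_weights list of `egg_selector_weights`.
#' @param cutoff cumulative-weight threshold (default 0.9).
#' @return object of class `egg_voting_result`: `avg_weights` (named,
#'   descending), `ranked_features`, `selected`, `cumulative_cutoff`,
#'   `per_method` (weight matrix).
#' @export
vote_and_select <- function(all_weights, cutoff = 0.9) {
  if (length(all_weights) == 0) stop("no selector results", call. = FALSE)
  stopifnot(cutoff > 0, cutoff <= 1)
  feats <- sort(unique(unlist(lapply(all_weights,
                                     function(w) names(w$weights)))))
  mat <- sapply(all_weights, function(w) {
    v <- stats::setNames(rep(0, length(feats)), feats)
    v[names(w$weights)] <- w$weights
    v
  })
  mat <- matrix(mat, nrow = length(feats),
                dimnames = list(feats, vapply(all_weights,
                                              `[[`, "", "method_name")))
  avg <- rowMeans(mat)
  avg <- avg / sum(avg)
  # descending weight, ties alphabetical (feats already sorted -> stable)
  ord <- order(-avg)
  avg <- avg[ord]
  n_sel <- which(cumsum(avg) >= cutoff - 1e-12)[1]
  structure(
    list(avg_weights = avg, ranked_features = names(avg),
         selected = names(avg)[seq_len(n_sel)],
         cumulative_cutoff = cutoff, per_method = mat),
    class = "egg_voting_result")
}

#' @export
print.egg_voting_result <- function(x, ...) {
  cat(sprintf("<egg_voting_result> %d/%d features at cutoff %.2f:\n",
              length(x$selected), length(x$ranked_features),
              x$cumulative_cutoff))
  print(round(x$avg_weights[x$selected], 4))
  invisible(x)
}

#' Run every base selector and vote
#'
#' @param X,y as in [run_selector()].
#' @param methods which base selectors to run (default all nine).
#' @param cutoff cumulative-weight cutoff for [vote_and_select()].
#' @param ... passed to [run_selector()].
#' @return an `egg_voting_result`.
#' @export
select_features <- function(X, y, methods = selector_methods(),
                            cutoff = 0.9, ...) {
  vote_and_select(lapply(methods, function(m) run_selector(m, X, y, ...)),
                  cutoff = cutoff)
}
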