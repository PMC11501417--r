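# Feature selection, base learners, two-stage stacked generalization with
# out-of-fold meta-features, and macro-averaged evaluation.

y01 <- function(y) as.integer(y == levels(y)[1])  # class A ("generalized") = 1

# one-way ANOVA F statistic of each column of X against binary y;
# constant columns score 0 by convention
anova_f_scores <- function(X, y) {
  yb <- y01(y)
  n <- length(yb)
  apply(X, 2, function(x) {
    mu <- mean(x)
    g <- tapply(x, yb, mean)
    cnt <- tapply(x, yb, length)
    ssb <- sum(cnt * (g - mu)^2)
    ssw <- sum((x - g[as.character(yb)])^2)
    dfb <- length(g) - 1L
    dfw <- n - length(g)
    if (ssw <= .Machine$double.eps || dfb == 0L) {
      if (ssb <= .Machine$double.eps) 0 else Inf
    } else {
      (ssb / dfb) / (ssw / dfw)
    }
  })
}

# plug-in mutual information (nats) of each binary column with binary y
mutual_info_scores <- function(X, y) {
  yb <- y01(y)
  n <- length(yb)
  apply(X, 2, function(x) {
    tab <- table(factor(x, levels = 0:1), factor(yb, levels = 0:1)) / n
    px <- rowSums(tab); py <- colSums(tab)
    mi <- 0
    for (i in 1:2) for (j in 1:2) {
      p <- tab[i, j]
      if (p > 0) mi <- mi + p * log(p / (px[i] * py[j]))
    }
    max(0, mi)
  })
}

rf_importance_scores <- function(X, y, seed = 1L, num.trees = 500L) {
  df <- as.data.frame(X)
  fit <- ranger::ranger(x = df, y = y, num.trees = num.trees,
                        importance = "impurity", seed = seed,
                        num.threads = 1L)
  imp <- fit$variable.importance
  imp[colnames(X)]
}

#' Select features from a binary symptom matrix
#'
#' Ranks features by one of four criteria and keeps the top `k`:
#' `kbest_anova` (one-way ANOVA F statistic of feature vs class),
#' `mutual_info` (plug-in mutual information of the 2x2 feature/label
#' table, in nats), `rf_importance` (random-forest impurity importance),
#' or `rfe` (recursive feature elimination: repeatedly refit a random
#' forest and drop the lowest-importance feature(s) until `k` remain).
#' Constant features score 0 by convention. With `k = ncol(X)` all methods
#' return the identity selection (ranked).
#'
#' @param X Binary feature matrix (documents x symptoms).
#' @param y Factor with levels `generalized`, `focal`.
#' @param method Selection criterion.
#' @param k Number of features to keep, `1 <= k <= ncol(X)`.
#' @param seed Seed for the forest-based criteria.
#' @param rfe_step Features eliminated per refit in `rfe` (default 1).
#' @return Integer vector of `k` column indices, best first.
#' @export
select_features <- function(X, y,
                            method = c("kbest_anova", "mutual_info",
                                       "rf_importance", "rfe"),
                            k, seed = 1L, rfe_step = 1L) {
  method <- match.arg(method)
  stopifnot(k >= 1L, k <= ncol(X))
  y <- as.factor(y)
  if (method == "rfe") {
    alive <- seq_len(ncol(X))
    while (length(alive) > k) {
      imp <- rf_importance_scores(X[, alive, drop = FALSE], y, seed = seed)
      drop_n <- min(rfe_step, length(alive) - k)
      worst <- order(imp)[seq_len(drop_n)]
      alive <- alive[-worst]
    }
    imp <- rf_importance_scores(X[, alive, drop = FALSE], y, seed = seed)
    return(alive[order(imp, decreasing = TRUE)])
  }
  scores <- switch(method,
    kbest_anova = anova_f_scores(X, y),
    mutual_info = mutual_info_scores(X, y),
    rf_importance = rf_importance_scores(X, y, seed = seed)
  )
  order(scores, decreasing = TRUE)[seq_len(k)]
}

#' Base learners for the stacked ensemble
#'
#' Each constructor returns a learner object with a `fit(X, y, seed)`
#' closure returning a fitted model and a `predict_prob(fit, X)` closure
#' returning the probability of the positive class (`generalized`). The
#' defaults mirror a practical roster: a single decision tree, a random
#' forest, and gradient-boosted trees.
#'
#' @param ... Passed on to the underlying engine (e.g. `num.trees`,
#'   `nrounds`, `max_depth`).
#' @return An object of class `episemio_learner`.
#' @name learners
NULL

new_learner <- function(name, fit, predict_prob) {
  structure(list(name = name, fit = fit, predict_prob = predict_prob),
            class = "episemio_learner")
}

#' @rdname learners
#' @export
learner_decision_tree <- function(...) {
  new_learner(
    "decision_tree",
    fit = function(X, y, seed = 1L) {
      df <- data.frame(.y = y, as.data.frame(X))
      with_seed(seed, rpart::rpart(.y ~ ., data = df, method = "class", ...))
    },
    predict_prob = function(fit, X) {
      p <- predict(fit, as.data.frame(X), type = "prob")
      unname(p[, "generalized"])
    })
}

#' @rdname learners
#' @export
learner_random_forest <- function(num.trees = 500L, ...) {
  new_learner(
    "random_forest",
    fit = function(X, y, seed = 1L) {
      ranger::ranger(x = as.data.frame(X), y = y, probability = TRUE,
                     num.trees = num.trees, seed = seed, num.threads = 1L, ...)
    },
    predict_prob = function(fit, X) {
      p <- predict(fit, as.data.frame(X), num.threads = 1L)$predictions
      unname(p[, "generalized"])
    })
}

#' @rdname learners
#' @export
learner_xgboost <- function(nrounds = 150L, max_depth = 4L, eta = 0.3, ...) {
  new_learner(
    "xgboost",
    fit = function(X, y, seed = 1L) {
      d <- xgboost::xgb.DMatrix(data = as.matrix(X), label = y01(y))
      params <- list(objective = "binary:logistic", max_depth = max_depth,
                     eta = eta, nthread = 1L, seed = seed, ...)
      xgboost::xgb.train(params = params, data = d, nrounds = nrounds,
                         verbose = 0)
    },
    predict_prob = function(fit, X) {
      as.numeric(predict(fit, xgboost::xgb.DMatrix(as.matrix(X))))
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stratified-ish random fold assignment with single-class-fold retry
make_folds <- function(y, n_folds, seed, max_tries = 5L) {
  n <- length(y)
  for (try in seq_len(max_tries)) {
    folds <- with_seed(seed + (try - 1L) * 1009L,
                       sample(rep_len(seq_len(n_folds), n)))
    ok <- all(vapply(seq_len(n_folds), function(f)
      length(unique(y[folds != f])) == 2L && sum(folds == f) > 0L, logical(1)))
    if (ok) return(folds)
  }
  stop("could not build ", n_folds, "-fold partition with both classes ",
       "in every training part after ", max_tries, " attempts")
}

#' Fit a two-stage stacked ensemble
#'
#' Stage 1: the training set is split into `n_folds` folds; each base
#' learner is fitted on the other folds and predicts (a) the held-out
#' fold, producing its out-of-fold meta-feature column over the whole
#' training set, and (b) the entire test set; the test meta-feature is the
#' mean of the fold models' test predictions. Stage 2: an L2-regularized
#' logistic regression (the meta-learner) is fitted on the out-of-fold
#' meta-features against the training labels and applied to the test
#' meta-features. Every training row is predicted exactly once
#' out-of-fold, so the meta-learner never sees a base prediction made by a
#' model that was trained on that row.
#'
#' @param train,test `episemio_feature_matrix` objects (see
#'   [split_train_test()]).
#' @param learners List of [learners] (default: XGBoost + random forest).
#' @param n_folds Number of stage-1 folds (default 5).
#' @param seed Integer seed controlling folds and learner fits.
#' @param meta_lambda Ridge penalty of the meta-learner (fixed, recorded in
#'   the model for reproducibility).
#' @return An `episemio_stack`: `meta_train` (n_train x learners matrix of
#'   out-of-fold probabilities), `meta_test`, `fold_assignment`,
#'   `meta_fit`, `test_prob` (probability of `generalized`), `test_pred`
#'   (hard labels at 0.5) and the configuration.
#' @export
fit_stack <- function(train, test, learners = list(learner_xgboost(),
                                                   learner_random_forest()),
                      n_folds = 5L, seed = 1L, meta_lambda = 0.01) {
  stopifnot(inherits(train, "episemio_feature_matrix"),
            inherits(test, "episemio_feature_matrix"))
  y <- train$y
  if (any(table(y) < n_folds))
    stop("need at least ", n_folds, " training rows per class")
  folds <- make_folds(y, n_folds, seed)
  n_train <- nrow(train$X); n_test <- nrow(test$X)
  L <- length(learners)
  meta_train <- matrix(NA_real_, n_train, L)
  meta_test <- matrix(0, n_test, L)
  colnames(meta_train) <- colnames(meta_test) <-
    vapply(learners, `[[`, character(1), "name")
  for (l in seq_len(L)) {
    lr <- learners[[l]]
    for (f in seq_len(n_folds)) {
      in_fold <- folds == f
      fit <- lr$fit(train$X[!in_fold, , drop = FALSE], y[!in_fold],
                    seed = seed + 17L * f + 101L * l)
      meta_train[in_fold, l] <-
        lr$predict_prob(fit, train$X[in_fold, , drop = FALSE])
      meta_test[, l] <- meta_test[, l] + lr$predict_prob(fit, test$X) / n_folds
    }
  }
  stopifnot(!anyNA(meta_train))
  if (all(apply(meta_train, 2, stats::var) < 1e-12)) {
    # no base model carries signal: intercept-only meta-learner
    p_hat <- mean(y01(y))
    meta_fit <- structure(list(p = p_hat), class = "episemio_meta_intercept")
    test_prob <- rep(p_hat, n_test)
  } else {
    # glmnet needs >= 2 columns; pad with a constant (coefficient-0) column
    pad <- function(m) if (ncol(m) >= 2L) m else cbind(m, .pad = 0)
    meta_fit <- glmnet::glmnet(pad(meta_train), y01(y), family = "binomial",
                               alpha = 0, lambda = meta_lambda)
    test_prob <- as.numeric(predict(meta_fit, pad(meta_test),
                                    type = "response"))
  }
  test_pred <- factor(ifelse(test_prob >= 0.5, "generalized", "focal"),
                      levels = c("generalized", "focal"))
  structure(list(meta_train = meta_train, meta_test = meta_test,
                 fold_assignment = folds, meta_fit = meta_fit,
                 test_prob = test_prob, test_pred = test_pred,
                 learners = colnames(meta_train), n_folds = n_folds,
                 seed = seed, meta_lambda = meta_lambda),
            class = "episemio_stack")
}

#' @export
print.episemio_stack <- function(x, ...) {
  cat("<episemio_stack> base: ", paste(x$learners, collapse = " + "),
      "; ", x$n_folds, "-fold out-of-fold meta-features; ridge logistic ",
      "meta-learner (lambda=", x$meta_lambda, ")\n", sep = "")
  invisible(x)
}

#' Confusion counts for binary classification
#'
#' @param pred,y Factors (or characters) over `{generalized, focal}`;
#'   `generalized` is class A, `focal` class B.
#' @return An `episemio_confusion` list with `tp_a`, `fp_a`, `fn_a`,
#'   `tp_b`, `fp_b`, `fn_b`. By construction `fp_a = fn_b` and
#'   `fn_a = fp_b`.
#' @export
confusion <- function(pred, y) {
  lv <- c("generalized", "focal")
  pred <- as.character(pred); y <- as.character(y)
  if (length(pred) != length(y)) stop("pred and y must have equal length")
  if (!all(pred %in% lv) || !all(y %in% lv))
    stop("labels must be 'generalized' or 'focal'")
  tp_a <- sum(pred == "generalized" & y == "generalized")
  fp_a <- sum(pred == "generalized" & y == "focal")
  fn_a <- sum(pred == "focal" & y == "generalized")
  tp_b <- sum(pred == "focal" & y == "focal")
  structure(list(tp_a = tp_a, fp_a = fp_a, fn_a = fn_a,
                 tp_b = tp_b, fp_b = fn_a, fn_b = fp_a),
            class = "episemio_confusion")
}

#' Macro-averaged precision, recall and F1
#'
#' Unweighted means over the two classes:
#' `P = (TP_A/(TP_A+FP_A) + TP_B/(TP_B+FP_B)) / 2`, recall analogously
#' with FN, and `F1 = 2PR/(P+R)`. A class with a zero denominator
#' contributes 0 to the average, with a warning.
#'
#' @param conf An [confusion()] object (or compatible list of counts).
#' @return List with `precision`, `recall`, `f1`.
#' @export
macro_metrics <- function(conf) {
  counts <- unlist(conf[c("tp_a", "fp_a", "fn_a", "tp_b", "fp_b", "fn_b")])
  if (all(counts == 0)) stop("all-zero confusion matrix")
  term <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (0/0); contributes 0"); 0 }
    else num / den
  }
  precision <- (term(conf$tp_a, conf$tp_a + conf$fp_a, "precision(A)") +
                term(conf$tp_b, conf$tp_b + conf$fp_b, "precision(B)")) / 2
  recall <- (term(conf$tp_a, conf$tp_a + conf$fn_a, "recall(A)") +
             term(conf$tp_b, conf$tp_b + conf$fn_b, "recall(B)")) / 2
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1)
}

#' Area under the ROC curve by the rank formulation
#'
#' Mann-Whitney AUC with midranks for ties: the probability that a random
#' `generalized` case scores higher than a random `focal` case. Scores are
#' the predicted probability of `generalized` (class A), which fixes the
#' ROC orientation.
#'
#' @param scores Numeric scores, higher meaning more likely `generalized`.
#' @param y Factor/character labels over `{generalized, focal}`; both
#'   classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, y) {
  y <- as.character(y)
  pos <- y == "generalized"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Generic grid search with k-fold cross-validation
#'
#' Utility for tuning a base learner: every row of `grid` parameterizes the
#' `learner_factory`, each candidate is scored by k-fold cross-validated
#' AUC on the training data, and the best row wins.
#'
#' @param X,y Training features and labels.
#' @param learner_factory Function taking one named list of parameters and
#'   returning an `episemio_learner`.
#' @param grid Data frame of candidate parameter combinations.
#' @param n_folds Folds for cross-validation.
#' @param seed Seed for fold assignment and fits.
#' @return List with `best` (parameter row), `scores` (mean CV AUC per
#'   row).
#' @export
cv_grid_search <- function(X, y, learner_factory, grid, n_folds = 5L,
                           seed = 1L) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
  y <- as.factor(y)
  folds <- make_folds(y, n_folds, seed)
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    lr <- do.call(learner_factory, as.list(grid[g, , drop = FALSE]))
    aucs <- vapply(seq_len(n_folds), function(f) {
      in_fold <- folds == f
      fit <- lr$fit(X[!in_fold, , drop = FALSE], y[!in_fold],
                    seed = seed + f)
      roc_auc(lr$predict_prob(fit, X[in_fold, , drop = FALSE]), y[in_fold])
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  list(best = grid[which.max(scores), , drop = FALSE], scores = scores)
}
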