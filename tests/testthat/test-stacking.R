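# planted design: one feature strongly class-dependent, the rest noise
planted_design <- function(n, seed, p1_a = 0.9, p1_b = 0.1, n_noise = 9) {
  set.seed(seed)
  y <- factor(sample(c("generalized", "focal"), n, replace = TRUE),
              levels = c("generalized", "focal"))
  X <- matrix(rbinom(n * (n_noise + 1), 1, 0.5), n, n_noise + 1)
  X[, 1] <- rbinom(n, 1, ifelse(y == "generalized", p1_a, p1_b))
  colnames(X) <- sprintf("f%02d", seq_len(n_noise + 1))
  list(X = X, y = y)
}

fm_of <- function(X, y) {
  ids <- sprintf("d%04d", seq_len(nrow(X)))
  rownames(X) <- ids
  structure(list(doc_ids = ids, X = X, y = y),
            class = "episemio_feature_matrix")
}

test_that("all four selection criteria rank the informative feature first", {
  for (seed in c(1, 2, 3, 4, 5)) {
    d <- planted_design(2000, seed)
    for (method in c("kbest_anova", "mutual_info", "rf_importance", "rfe")) {
      top <- select_features(d$X, d$y, method, k = 1, seed = seed,
                             rfe_step = 2L)
      expect_equal(top, 1L, info = paste(method, seed))
    }
  }
  # k = ncol returns every index
  d <- planted_design(300, 9)
  expect_setequal(select_features(d$X, d$y, "kbest_anova", k = ncol(d$X)),
                  seq_len(ncol(d$X)))
})

test_that("mutual information obeys its identities", {
  d <- planted_design(4000, 21)
  mi <- episemio:::mutual_info_scores(d$X, d$y)
  # independent features carry ~0 bits; the label itself carries H(y)
  expect_lt(max(mi[-1]), 0.01)
  Xy <- cbind(d$X, yfeat = as.integer(d$y == "generalized"))
  mi2 <- episemio:::mutual_info_scores(Xy, d$y)
  p <- mean(d$y == "generalized")
  H <- -p * log(p) - (1 - p) * log(1 - p)
  expect_equal(unname(mi2["yfeat"]), H, tolerance = 1e-12)
  # constant feature scores 0 (ANOVA F convention)
  Xc <- cbind(d$X, const = 0L)
  expect_equal(unname(episemio:::anova_f_scores(Xc, d$y)["const"]), 0)
})

test_that("stacking produces exactly one out-of-fold prediction per row", {
  d <- planted_design(400, 3)
  sp <- split_train_test(fm_of(d$X, d$y), 0.7, seed = 1)
  st <- fit_stack(sp$train, sp$test, n_folds = 5, seed = 7)
  expect_equal(dim(st$meta_train), c(length(sp$train$y), 2))
  expect_false(anyNA(st$meta_train))
  expect_equal(sort(unique(st$fold_assignment)), 1:5)
  expect_equal(length(st$test_prob), length(sp$test$y))
  expect_true(all(st$test_prob >= 0 & st$test_prob <= 1))
  # reproducibility: same data and seed give identical meta-features
  st2 <- fit_stack(sp$train, sp$test, n_folds = 5, seed = 7)
  expect_identical(st$meta_train, st2$meta_train)
  expect_identical(st$test_prob, st2$test_prob)
})

test_that("an uninformative base model yields majority-class accuracy", {
  constant_learner <- function() {
    episemio:::new_learner("flat",
      fit = function(X, y, seed = 1L) NULL,
      predict_prob = function(fit, X) rep(0.5, nrow(X)))
  }
  d <- planted_design(400, 5)
  sp <- split_train_test(fm_of(d$X, d$y), 0.7, seed = 2)
  st <- fit_stack(sp$train, sp$test, learners = list(constant_learner()),
                  n_folds = 5, seed = 1)
  acc <- mean(st$test_pred == sp$test$y)
  majority <- max(table(sp$test$y)) / length(sp$test$y)
  expect_lt(abs(acc - majority), 0.1)
})

test_that("a separable synthetic cohort is classified nearly perfectly", {
  b <- generate_cohort(cohort_spec(n_docs = 600, seed = 8))
  sp <- split_train_test(b$planted, 0.7, seed = 4)
  st <- fit_stack(sp$train, sp$test, seed = 4)
  m <- macro_metrics(confusion(st$test_pred, sp$test$y))
  expect_gt(m$f1, 0.9)
  expect_gt(roc_auc(st$test_prob, sp$test$y), 0.95)
})

test_that("macro metrics follow the two-class averaging formulas", {
  conf <- list(tp_a = 50, fp_a = 10, fn_a = 20, tp_b = 80, fp_b = 20,
               fn_b = 10)
  m <- macro_metrics(conf)
  expect_equal(m$precision, (50 / 60 + 80 / 100) / 2)  # 0.8167
  expect_equal(round(m$precision, 4), 0.8167)
  # perfect classifier
  perf <- macro_metrics(list(tp_a = 5, fp_a = 0, fn_a = 0, tp_b = 7,
                             fp_b = 0, fn_b = 0))
  expect_equal(unlist(perf), c(precision = 1, recall = 1, f1 = 1))
  # symmetric confusion: P = R implies F1 = P
  symm <- macro_metrics(list(tp_a = 40, fp_a = 10, fn_a = 10, tp_b = 40,
                             fp_b = 10, fn_b = 10))
  expect_equal(symm$f1, symm$precision)
  expect_error(macro_metrics(list(tp_a = 0, fp_a = 0, fn_a = 0, tp_b = 0,
                                  fp_b = 0, fn_b = 0)), "all-zero")
})

test_that("macro metrics and confusion agree with independent recomputation", {
  set.seed(33)
  for (rep in 1:25) {
    n <- sample(10:100, 1)
    y <- sample(c("generalized", "focal"), n, replace = TRUE)
    pred <- sample(c("generalized", "focal"), n, replace = TRUE)
    if (length(unique(y)) < 2 || length(unique(pred)) < 2) next
    cf <- confusion(pred, y)
    # brute-force recount
    expect_equal(cf$tp_a, sum(pred == "generalized" & y == "generalized"))
    expect_equal(cf$fp_a, cf$fn_b)
    expect_equal(cf$fn_a, cf$fp_b)
    want <- bf_macro(pred, y)
    got <- suppressWarnings(macro_metrics(cf))
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
    expect_equal(got$f1, want$f1)
  }
  expect_error(confusion(c("generalized", "x"), c("focal", "focal")),
               "labels")
})

test_that("rank-based AUC is correct, tie-safe and monotone-invariant", {
  y <- c(rep("generalized", 3), rep("focal", 3))
  expect_equal(roc_auc(c(.9, .8, .7, .3, .2, .1), y), 1)
  expect_equal(roc_auc(c(.1, .2, .3, .7, .8, .9), y), 0)
  expect_equal(roc_auc(rep(0.5, 6), y), 0.5)  # all tied: midranks give 1/2
  set.seed(44)
  s <- runif(200); yy <- sample(c("generalized", "focal"), 200, replace = TRUE)
  expect_equal(roc_auc(s, yy), roc_auc(qlogis(s), yy))  # monotone transform
  # cross-check against an established ROC implementation
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = yy, predictor = s, levels = c("focal", "generalized"),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(s, yy), ref)
  expect_error(roc_auc(s, rep("focal", 200)), "both classes")
})

test_that("grid search picks the better-regularized candidate", {
  d <- planted_design(300, 6)
  grid <- data.frame(num.trees = c(5L, 100L))
  out <- cv_grid_search(d$X, d$y, learner_random_forest, grid,
                        n_folds = 3, seed = 2)
  expect_equal(nrow(out$best), 1)
  expect_length(out$scores, 2)
  expect_true(all(out$scores > 0.5))
})
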