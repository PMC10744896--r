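test_that("confusion metrics match hand-computed values", {
  # TP=4, FN=1, TN=9, FP=1 (15 subjects)
  y <- c(rep("case", 5), rep("control", 10))
  score <- c(0.9, 0.8, 0.7, 0.6, 0.2,            # one case missed
             0.7, rep(0.1, 9))                   # one control hit
  m <- compute_metrics(y, score)
  expect_equal(m$tp, 4); expect_equal(m$fn, 1)
  expect_equal(m$tn, 9); expect_equal(m$fp, 1)
  expect_equal(m$accuracy, 13 / 15)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$f1, 2 * 0.8 * 0.8 / 1.6)

  # perfect scores: everything 1
  mp <- compute_metrics(y, as.numeric(y == "case"))
  expect_true(all(unlist(mp[c("accuracy", "precision", "recall",
                              "specificity", "f1", "auroc")]) == 1))

  # constant scores: all ties, AUROC exactly 0.5
  mc <- compute_metrics(y, rep(0.4, 15))
  expect_equal(mc$auroc, 0.5)

  expect_error(compute_metrics(rep("case", 5), runif(5)), "single class")
})

test_that("rank AUROC equals the brute-force concordant-pair count", {
  set.seed(10)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    y <- sample(c("case", "control"), n, replace = TRUE,
                prob = c(0.4, 0.6))
    if (length(unique(y)) < 2) next
    score <- round(runif(n), 2)   # rounding forces ties
    expect_equal(compute_metrics(y, score)$auroc, auroc_oracle(y, score))
  }
})

test_that("stratified folds partition every subject exactly once per repeat", {
  set.seed(11)
  y <- c(rep("case", 13), rep("control", 17))
  fold <- neckpose:::stratified_folds(y, 5)
  expect_length(fold, 30)
  expect_setequal(unique(fold), 1:5)
  for (f in 1:5) expect_gte(sum(fold == f & y == "case"), 2)
  expect_error(neckpose:::stratified_folds(rep(c("case", "control"),
                                               c(3, 27)), 5),
               "stratification impossible")
})

test_that("nested CV covers each subject once per repeat and is seed-reproducible", {
  set.seed(12)
  n <- 24
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- rep(c("case", "control"), each = n / 2)
  X[, 1] <- X[, 1] + 3.5 * (y == "case")
  cv1 <- nested_cv(X, y, model_spec("random_forest"), repeats = 2, seed = 42)
  cv2 <- nested_cv(X, y, model_spec("random_forest"), repeats = 2, seed = 42)
  expect_identical(cv1$folds, cv2$folds)

  for (r in 1:2) {
    det <- Filter(function(d) d$repeat_ == r, cv1$fold_detail)
    tested <- sort(unlist(lapply(det, `[[`, "test_idx")))
    expect_identical(tested, 1:n)   # every subject tested exactly once
  }
  expect_gte(cv1$summary[["auroc"]], 0.8)  # strong planted effect
})

test_that("per-fold selection never sees test subjects", {
  set.seed(13)
  n <- 30
  X <- matrix(rnorm(n * 25), n, 25, dimnames = list(NULL, paste0("f", 1:25)))
  y <- rep(c("case", "control"), each = n / 2)
  X[, 1] <- X[, 1] + 3 * (y == "case")
  cv <- nested_cv(X, y, model_spec("random_forest"), repeats = 1, seed = 3,
                  selection = "per_fold")
  for (d in cv$fold_detail) {
    expect_length(intersect(d$train_idx, d$test_idx), 0)
    expect_false(is.null(d$selected))
    expect_identical(sort(union(d$train_idx, d$test_idx)), 1:n)
  }
})

test_that("the inner grid search picks hyperparameters from the grid", {
  set.seed(14)
  n <- 30
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- rep(c("case", "control"), each = n / 2)
  X[, 1] <- X[, 1] + 2 * (y == "case")
  spec <- model_spec("random_forest",
                     grid = list(n_estimators = c(50, 100),
                                 max_features = c("sqrt", "log2")))
  cv <- nested_cv(X, y, spec, repeats = 1, seed = 5)
  for (d in cv$fold_detail) {
    expect_true(d$params$n_estimators %in% c(50, 100))
    expect_true(d$params$max_features %in% c("sqrt", "log2"))
  }
})

test_that("every model family fits, predicts probabilities, and is seed-stable", {
  set.seed(15)
  n <- 30
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- rep(c("case", "control"), each = n / 2)
  X[, 1] <- X[, 1] + 2 * (y == "case")
  for (fam in c("random_forest", "logistic_regression",
                "gradient_boosted_trees", "bagging_rf", "adaboost_rf")) {
    set.seed(99); m1 <- fit_model(model_spec(fam), X, y)
    p1 <- predict(m1, X)
    expect_true(all(p1 >= 0 & p1 <= 1), info = fam)
    set.seed(99); m2 <- fit_model(model_spec(fam), X, y)
    expect_equal(p1, predict(m2, X), info = fam)
    expect_gte(compute_metrics(y, p1)$auroc, 0.8)  # in-sample, easy signal
  }
})

test_that("the final model refuses tiny cohorts and ranks the planted feature", {
  set.seed(16)
  n <- 40
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- rep(c("case", "control"), each = n / 2)
  X[, "f1"] <- X[, "f1"] + 3 * (y == "case")
  expect_error(train_final(X[1:8, ], y[1:8]), "fewer than 10")

  fm <- train_final(X, y, seed = 1, n_splits = 3, n_perm = 2)
  expect_s3_class(fm$model, "neckpose_model")
  expect_identical(fm$importance$feature[1], "f1")

  # ablation: removing the informative feature costs AUROC
  set.seed(2)
  cv_full <- nested_cv(X, y, model_spec("random_forest"), repeats = 1,
                       seed = 2)
  cv_abl <- nested_cv(X[, -1], y, model_spec("random_forest"), repeats = 1,
                      seed = 2)
  expect_gte(cv_full$summary[["auroc"]] - cv_abl$summary[["auroc"]], 0.05)
})
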