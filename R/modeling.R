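# Evaluation harness: confusion-matrix metrics and rank-based AUROC, repeated
# stratified nested cross-validation with inner-loop grid search (and optional
# per-fold feature selection, so no test subject ever influences selection or
# tuning), and the final bagged-random-forest model with permutation
# importance.

#' Confusion-matrix metrics and AUROC
#'
#' Scores are thresholded at `threshold` (predicted case iff score >=
#' threshold) for the confusion metrics; AUROC is computed by the rank
#' (Mann-Whitney) rule, so tied scores contribute 1/2. Precision and F1 are
#' defined as 0 when their denominator is 0.
#'
#' @param y_true labels (`"case"`/`"control"`); both classes must be present.
#' @param y_score numeric scores (probability of case).
#' @param threshold classification threshold on the score (default 0.5).
#' @return Named list: `tp`, `fp`, `tn`, `fn`, `accuracy`, `precision`,
#'   `recall`, `specificity`, `f1`, `auroc`.
#' @export
compute_metrics <- function(y_true, y_score, threshold = 0.5) {
  yt <- .as_y(y_true)
  stopifnot(length(yt) == length(y_score), !anyNA(y_score))
  if (nlevels(droplevels(yt)) < 2)
    stop("y_true contains a single class; AUROC is undefined")
  pos <- yt == "case"
  pred <- y_score >= threshold
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  tn <- sum(!pred & !pos); fn <- sum(!pred & pos)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  r <- rank(y_score)
  auroc <- (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
    (sum(pos) * sum(!pos))
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / length(yt),
       precision = precision, recall = recall,
       specificity = tn / (tn + fp), f1 = f1, auroc = auroc)
}

# Stratified fold assignment: within each class, subjects are shuffled and
# dealt round-robin over k folds.
stratified_folds <- function(y, k) {
  yf <- as.character(y)
  if (min(table(yf)) < k)
    stop("stratification impossible: a class has fewer than ", k, " subjects")
  fold <- integer(length(yf))
  for (cl in unique(yf)) {
    idx <- sample(which(yf == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.metric_names <- c("accuracy", "precision", "recall", "specificity",
                   "f1", "auroc")

# inner grid search: mean inner-fold AUROC per candidate; returns best params
.grid_search <- function(spec, X, y, inner) {
  if (length(spec$grid) == 0) return(spec$params)
  cand <- expand.grid(spec$grid, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  k <- min(inner, min(table(as.character(y))))
  if (k < 2) return(spec$params)
  fold <- stratified_folds(y, k)
  score <- vapply(seq_len(nrow(cand)), function(ci) {
    params <- utils::modifyList(spec$params, as.list(cand[ci, , drop = FALSE]))
    sp <- model_spec(spec$family, params = params)
    mean(vapply(seq_len(k), function(f) {
      tr <- fold != f
      m <- fit_model(sp, X[tr, , drop = FALSE], y[tr])
      compute_metrics(y[!tr],
                      predict(m, X[!tr, , drop = FALSE]))$auroc
    }, numeric(1)))
  }, numeric(1))
  utils::modifyList(spec$params,
                    as.list(cand[which.max(score), , drop = FALSE]))
}

#' Repeated stratified nested cross-validation
#'
#' Outer stratified k-fold estimates generalization performance; for each
#' outer training fold, an inner stratified k-fold grid search (scored by
#' mean inner AUROC) picks the hyperparameters, the model is refit on the
#' whole outer training fold, and metrics are computed on the outer test
#' fold. The whole procedure is repeated with reshuffled folds (repeat r
#' uses seed `seed + r - 1`) and the per-fold metrics are averaged within
#' and then across repeats.
#'
#' Feature selection scope: `"per_fold"` reruns the dual U-test/Lasso
#' selection inside every outer training fold (leakage-free; the default
#' when `selection` is requested), `"global"` selects once on all subjects
#' before cross-validation (matches a whole-cohort screening analysis but
#' lets test subjects influence selection — flagged in the result),
#' `"none"` uses all columns of `X`.
#'
#' @param X numeric feature matrix (subjects x features) with column names.
#' @param y labels (`"case"`/`"control"`).
#' @param spec a [model_spec()].
#' @param outer,inner,repeats fold counts and repetitions (defaults 5, 5, 5).
#' @param seed integer; the only source of randomness.
#' @param selection `"none"`, `"per_fold"` or `"global"`.
#' @param alpha U-test cutoff used when selection runs.
#' @return A `nested_cv` object: `folds` (data.frame of per-repeat, per-fold
#'   confusion counts and metrics), `fold_detail` (per fold: train/test
#'   indices, selected features, chosen hyperparameters), `summary` (metric
#'   means over all folds), `by_repeat` (metric means per repeat), and the
#'   call settings.
#' @export
nested_cv <- function(X, y, spec = model_spec("random_forest"),
                      outer = 5, inner = 5, repeats = 5, seed = 1L,
                      selection = c("none", "per_fold", "global"),
                      alpha = 0.01) {
  selection <- match.arg(selection)
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(length(y) == nrow(X))
  if (min(table(y)) < outer)
    stop("need at least ", outer, " subjects per class for ", outer,
         "-fold stratified CV")

  if (selection == "global") {
    set.seed(seed)
    sel_global <- select_features(X, y, alpha = alpha, seed = seed,
                                  schema = colnames(X))
    if (length(sel_global$union) == 0)
      stop("global selection returned no features")
  }

  rows <- list(); detail <- list()
  for (r in seq_len(repeats)) {
    set.seed(seed + r - 1L)
    fold <- stratified_folds(y, outer)
    for (f in seq_len(outer)) {
      tr <- which(fold != f); te <- which(fold == f)
      feats <- colnames(X)
      sel_n <- NA_integer_
      if (selection == "per_fold") {
        sel <- select_features(X[tr, , drop = FALSE], y[tr], alpha = alpha,
                               seed = seed + r - 1L, schema = colnames(X))
        feats <- if (length(sel$union)) sel$union else colnames(X)
        sel_n <- length(sel$union)
      } else if (selection == "global") {
        feats <- sel_global$union
        sel_n <- length(feats)
      }
      Xtr <- X[tr, feats, drop = FALSE]
      params <- .grid_search(spec, Xtr, y[tr], inner)
      m <- fit_model(model_spec(spec$family, params = params), Xtr, y[tr])
      sc <- predict(m, X[te, feats, drop = FALSE])
      met <- compute_metrics(y[te], sc)
      rows[[length(rows) + 1]] <-
        data.frame(repeat_ = r, fold = f, n_test = length(te),
                   as.data.frame(met))
      detail[[length(detail) + 1]] <-
        list(repeat_ = r, fold = f, train_idx = tr, test_idx = te,
             selected = if (selection == "none") NULL else feats,
             n_selected = sel_n, params = params)
    }
  }
  folds <- do.call(rbind, rows)
  by_repeat <- stats::aggregate(folds[.metric_names],
                                by = list(repeat_ = folds$repeat_), mean)
  structure(list(
    folds = folds, fold_detail = detail,
    summary = colMeans(folds[.metric_names]),
    by_repeat = by_repeat,
    family = spec$family, selection = selection,
    outer = outer, inner = inner, repeats = repeats, seed = seed
  ), class = "nested_cv")
}

#' @export
print.nested_cv <- function(x, ...) {
  cat(sprintf(
    "<nested_cv> %s, %d-fold stratified outer, %d repeat(s), selection: %s\n",
    x$family, x$outer, x$repeats, x$selection))
  print(round(x$summary, 3))
  invisible(x)
}

#' @export
summary.nested_cv <- function(object, ...) {
  cat("Repeated stratified nested cross-validation\n")
  cat(sprintf("  model: %s   outer %d-fold x %d repeats   selection: %s\n",
              object$family, object$outer, object$repeats, object$selection))
  cat("\nPer-repeat means:\n")
  print(cbind(repeat_ = object$by_repeat$repeat_,
              round(object$by_repeat[.metric_names], 3)), row.names = FALSE)
  sds <- apply(object$folds[.metric_names], 2, stats::sd)
  cat("\nOverall mean (SD over folds):\n")
  for (m in .metric_names)
    cat(sprintf("  %-12s %.3f (%.3f)\n", m, object$summary[[m]], sds[[m]]))
  invisible(object)
}

#' Permutation importance
#'
#' Mean held-out score degradation when one feature column is permuted,
#' repeated over `n_splits` stratified 80/20 splits: the model is refit on
#' each training part and every feature is permuted `n_perm` times in the
#' held-out part. The default score is the Brier score (a strictly proper
#' score: permuting any feature the model uses degrades it, even when the
#' holdout stays perfectly rank-separated and an AUROC drop would be 0 for
#' every feature); `metric = "auroc"` scores by AUROC drop instead.
#'
#' @param spec a [model_spec()].
#' @param X,y feature matrix and labels.
#' @param n_splits stratified splits to average over (default 5).
#' @param n_perm permutations per feature per split (default 3).
#' @param metric `"brier"` (default) or `"auroc"`.
#' @param seed integer seed.
#' @return data.frame with `feature` and `importance` (mean score
#'   degradation: Brier increase or AUROC drop), sorted decreasing.
#' @export
permutation_importance <- function(spec, X, y, n_splits = 5, n_perm = 3,
                                   metric = c("brier", "auroc"), seed = 1L) {
  metric <- match.arg(metric)
  X <- as.matrix(X); y <- as.character(y)
  # degradation of the score when scores `sc` replace the baseline
  degradation <- function(yte, sc_base, sc) {
    if (metric == "brier")
      mean((sc - (yte == "case"))^2) - mean((sc_base - (yte == "case"))^2)
    else
      compute_metrics(yte, sc_base)$auroc - compute_metrics(yte, sc)$auroc
  }
  set.seed(seed)
  drops <- matrix(0, ncol(X), n_splits, dimnames = list(colnames(X), NULL))
  fold <- stratified_folds(y, n_splits)
  for (s in seq_len(n_splits)) {
    tr <- fold != s; te <- !tr
    m <- fit_model(spec, X[tr, , drop = FALSE], y[tr])
    Xte <- X[te, , drop = FALSE]
    sc_base <- predict(m, Xte)
    for (j in seq_len(ncol(X))) {
      d <- vapply(seq_len(n_perm), function(...) {
        Xp <- Xte
        Xp[, j] <- sample(Xp[, j])
        degradation(y[te], sc_base, predict(m, Xp))
      }, numeric(1))
      drops[j, s] <- mean(d)
    }
  }
  imp <- data.frame(feature = colnames(X), importance = rowMeans(drops))
  imp <- imp[order(-imp$importance), ]
  rownames(imp) <- NULL
  imp
}

#' Fit the final bagged-random-forest model
#'
#' Fits `spec` (by default the bagging ensemble of random forests) on the
#' full cohort and ranks features by [permutation_importance()].
#'
#' @param X,y feature matrix and labels (at least 10 subjects).
#' @param spec a [model_spec()] (default `bagging_rf`).
#' @param seed integer seed (same seed, same model and predictions).
#' @param importance compute the permutation-importance ranking
#'   (default TRUE).
#' @param ... passed to [permutation_importance()].
#' @return A `final_model`: list with `model` (fitted `neckpose_model`,
#'   see [fit_model()]) and `importance` (ranking data.frame or NULL).
#' @export
train_final <- function(X, y, spec = model_spec("bagging_rf"), seed = 1L,
                        importance = TRUE, ...) {
  X <- as.matrix(X)
  if (nrow(X) < 10)
    stop("refusing to fit the final model on fewer than 10 subjects: ",
         "the ensemble is unstable at this size")
  imp <- if (importance)
    permutation_importance(spec, X, y, seed = seed, ...) else NULL
  set.seed(seed)
  model <- fit_model(spec, X, y)
  structure(list(model = model, importance = imp, seed = seed),
            class = "final_model")
}

#' @export
print.final_model <- function(x, ...) {
  print(x$model)
  if (!is.null(x$importance)) {
    cat("Top features by permutation importance (AUROC drop):\n")
    print(utils::head(x$importance, 10), row.names = FALSE)
  }
  invisible(x)
}

#' @export
predict.final_model <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}
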