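# Dual feature selection: two-sided Mann-Whitney U tests (case vs control,
# p < alpha, no multiple-testing correction -- deliberately, to match the
# screening step this pipeline reproduces) and an L1-penalised logistic model
# whose nonzero coefficients define the Lasso set. The union of the two sets
# is the model's training feature set.

#' Mann-Whitney U-test feature screen
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of each feature between
#' cases and controls; features with p below `alpha` are selected. The exact
#' null distribution is used when both groups have at most 8 subjects and the
#' feature is tie-free; otherwise the normal approximation with tie and
#' continuity correction. Features constant across all subjects are skipped
#' with a warning (their p-value is undefined).
#'
#' @param X numeric matrix or data.frame of features (subjects x features).
#' @param y labels: factor or character with values `"case"`/`"control"`.
#' @param alpha significance cutoff (default 0.01).
#' @return List with `selected` (feature names, canonical order) and
#'   `p_values` (named vector over all testable features).
#' @export
utest_select <- function(X, y, alpha = 0.01) {
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(all(y %in% c("case", "control")))
  if (min(table(y)) < 2) stop("need at least 2 subjects per class")
  if (anyNA(X)) stop("feature matrix contains missing values")
  case <- y == "case"
  n_small <- max(table(y)) <= 8
  pv <- vapply(colnames(X), function(f) {
    a <- X[case, f]; b <- X[!case, f]
    if (stats::var(c(a, b)) == 0) return(NA_real_)
    exact <- n_small && !anyDuplicated(c(a, b))
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
  }, numeric(1))
  if (anyNA(pv)) {
    warning("skipping constant feature(s): ",
            paste(names(pv)[is.na(pv)], collapse = ", "))
  }
  list(selected = names(pv)[!is.na(pv) & pv < alpha], p_values = pv[!is.na(pv)])
}

#' Lasso feature selection
#'
#' L1-penalised logistic regression on internally standardized features; the
#' penalty is chosen by cross-validation (deviance loss, `lambda.min`) and
#' the selected set is every feature with an exactly nonzero coefficient at
#' that penalty.
#'
#' @inheritParams utest_select
#' @param nfolds cross-validation folds for the penalty path (default 5).
#' @param seed integer seed controlling the fold assignment.
#' @return List with `selected` (feature names) and `weights` (named nonzero
#'   coefficients). An empty selection is returned with a warning.
#' @export
lasso_select <- function(X, y, nfolds = 5, seed = 1L) {
  X <- as.matrix(X)
  y01 <- as.integer(as.character(y) == "case")
  if (length(unique(y01)) < 2) stop("need both classes for the Lasso")
  # drop constant columns: they carry no information and break standardization
  keep <- apply(X, 2, stats::var) > 0
  Xk <- X[, keep, drop = FALSE]
  set.seed(seed)
  fit <- glmnet::cv.glmnet(Xk, y01, family = "binomial", alpha = 1,
                           standardize = TRUE, nfolds = nfolds)
  beta <- stats::coef(fit, s = "lambda.min")[-1, 1]  # drop intercept
  nz <- beta[beta != 0]
  if (length(nz) == 0)
    warning("Lasso selected no features at the cross-validated penalty")
  list(selected = names(nz), weights = nz)
}

#' Combine the two selections
#'
#' Set algebra on the U-test and Lasso selections; all sets are returned in
#' canonical order (the column order of `schema`).
#'
#' @param utest result of [utest_select()] (or a character vector of names).
#' @param lasso result of [lasso_select()] (or a character vector of names).
#' @param schema character vector fixing the canonical feature order
#'   (default [feature_schema()]).
#' @return `selection_result`: list with `utest_selected`, `lasso_selected`,
#'   `intersection`, `union`, plus `p_values` / `weights` when available.
#' @export
combine_selection <- function(utest, lasso, schema = feature_schema()) {
  u <- if (is.list(utest)) utest$selected else utest
  l <- if (is.list(lasso)) lasso$selected else lasso
  canon <- function(s) schema[schema %in% s]
  structure(list(
    utest_selected = canon(u),
    lasso_selected = canon(l),
    intersection = canon(intersect(u, l)),
    union = canon(union(u, l)),
    p_values = if (is.list(utest)) utest$p_values,
    weights = if (is.list(lasso)) lasso$weights
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> U-test %d, Lasso %d, intersection %d, union %d features\n",
    length(x$utest_selected), length(x$lasso_selected),
    length(x$intersection), length(x$union)))
  invisible(x)
}

#' One-call dual feature selection
#'
#' Runs [utest_select()] and [lasso_select()] on the same data and combines
#' them. This is the `global` selection scope: selection sees all subjects,
#' as in a screening analysis on a full cohort. For unbiased performance
#' estimates use the `per_fold` scope of [nested_cv()], which reselects
#' inside every training fold.
#'
#' @inheritParams utest_select
#' @inheritParams lasso_select
#' @param schema canonical feature order.
#' @return A `selection_result` (see [combine_selection()]).
#' @export
select_features <- function(X, y, alpha = 0.01, seed = 1L,
                            schema = colnames(as.matrix(X))) {
  u <- utest_select(X, y, alpha = alpha)
  l <- lasso_select(X, y, seed = seed)
  combine_selection(u, l, schema = schema)
}
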