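# Classifier families behind a single fit/predict interface. Random forests
# come from randomForest, gradient-boosted trees from xgboost, the logistic
# model is ridge-penalised glmnet (p can exceed n); the sklearn-style bagging
# ensemble (bootstrap over both samples and features) and the SAMME AdaBoost
# of random forests are implemented here.

.model_families <- c("random_forest", "gradient_boosted_trees", "gradboost",
                     "logistic_regression", "bagging_rf", "adaboost_rf")

#' Specify a classifier
#'
#' @param family one of `random_forest`, `gradient_boosted_trees` (alias
#'   `gradboost`), `logistic_regression`, `bagging_rf` (bagging ensemble of
#'   random forests), `adaboost_rf` (SAMME AdaBoost of random forests).
#' @param params named list overriding the family defaults. Defaults:
#'   random forest `n_estimators = 100`, `max_features = "log2"`; bagging
#'   `n_estimators = 50`, `max_samples = 0.5`, `max_features = 0.5`,
#'   `bootstrap = TRUE`, `bootstrap_features = TRUE` (base learner: the
#'   default random forest); AdaBoost `n_estimators = 10`; boosted trees
#'   `nrounds = 100`, `max_depth = 3`, `eta = 0.1`; logistic ridge penalty
#'   `lambda = 1/n`.
#' @param grid named list of candidate vectors for inner-loop tuning, e.g.
#'   `list(n_estimators = c(50, 100, 200), max_features = c("sqrt", "log2"))`.
#'   An empty grid means the defaults are used without tuning.
#' @return A `model_spec` object.
#' @export
model_spec <- function(family = "bagging_rf", params = list(), grid = list()) {
  family <- match.arg(family, .model_families)
  if (family == "gradboost") family <- "gradient_boosted_trees"
  defaults <- switch(family,
    random_forest = list(n_estimators = 100, max_features = "log2"),
    bagging_rf = list(n_estimators = 50, max_samples = 0.5,
                      max_features = 0.5, bootstrap = TRUE,
                      bootstrap_features = TRUE,
                      base_n_estimators = 100, base_max_features = "log2"),
    adaboost_rf = list(n_estimators = 10,
                       base_n_estimators = 100, base_max_features = "log2"),
    gradient_boosted_trees = list(nrounds = 100, max_depth = 3, eta = 0.1),
    logistic_regression = list(lambda = NULL))
  p <- utils::modifyList(defaults, params)
  structure(list(family = family, params = p, grid = grid),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$family, "\n  params:",
      paste(names(x$params), vapply(x$params, function(v)
        paste(format(v), collapse = "/"), character(1)),
        sep = "=", collapse = ", "), "\n")
  if (length(x$grid))
    cat("  grid over:", paste(names(x$grid), collapse = ", "), "\n")
  invisible(x)
}

.mtry <- function(max_features, p) {
  if (is.numeric(max_features)) return(max(1L, min(p, as.integer(max_features))))
  switch(match.arg(max_features, c("log2", "sqrt")),
         log2 = max(1L, floor(log2(p))),
         sqrt = max(1L, floor(sqrt(p))))
}

.as_y <- function(y) factor(as.character(y), levels = c("control", "case"))

.fit_rf <- function(X, yf, n_estimators, max_features) {
  randomForest::randomForest(x = X, y = yf,
                             ntree = as.integer(n_estimators),
                             mtry = .mtry(max_features, ncol(X)))
}

#' Fit a classifier
#'
#' Fits `spec` on a numeric feature matrix. The positive class is `"case"`.
#' Fits are deterministic given the R random seed in force at the call.
#'
#' @param spec a [model_spec()].
#' @param X numeric matrix (subjects x features), column names required.
#' @param y labels (`"case"`/`"control"`).
#' @return A fitted `neckpose_model`; use [predict()] with
#'   `type = "prob"` (probability of case) or `type = "class"`.
#' @export
fit_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must have column names")
  yf <- .as_y(y)
  if (nlevels(droplevels(yf)) < 2) stop("need both classes to fit")
  p <- spec$params
  fit <- switch(spec$family,
    random_forest = .fit_rf(X, yf, p$n_estimators, p$max_features),
    logistic_regression = {
      lam <- if (is.null(p$lambda)) 1 / nrow(X) else p$lambda
      glmnet::glmnet(X, yf, family = "binomial", alpha = 0, lambda = lam,
                     standardize = TRUE)
    },
    gradient_boosted_trees =
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = as.integer(p$max_depth), eta = p$eta,
                      nthread = 1),
        data = xgboost::xgb.DMatrix(X, label = as.integer(yf == "case")),
        nrounds = as.integer(p$nrounds), verbose = 0),
    bagging_rf = .fit_bagging_rf(X, yf, p),
    adaboost_rf = .fit_adaboost_rf(X, yf, p))
  structure(list(family = spec$family, spec = spec, fit = fit,
                 features = colnames(X)),
            class = "neckpose_model")
}

# sklearn-style bagging: each of n_estimators base learners sees a bootstrap
# sample of round(max_samples * n) subjects and a bootstrap draw (with
# replacement when bootstrap_features) of round(max_features * p) features.
.fit_bagging_rf <- function(X, yf, p) {
  n <- nrow(X); np <- ncol(X)
  ns <- max(2L, round(p$max_samples * n))
  nf <- max(1L, round(p$max_features * np))
  bags <- vector("list", p$n_estimators)
  for (b in seq_len(p$n_estimators)) {
    repeat {  # resample until both classes present (tiny-n guard)
      idx <- if (isTRUE(p$bootstrap)) sample(n, ns, replace = TRUE)
             else sample(n, ns)
      if (nlevels(droplevels(yf[idx])) == 2) break
    }
    fidx <- if (isTRUE(p$bootstrap_features)) sample(np, nf, replace = TRUE)
            else sample(np, nf)
    Xb <- X[idx, fidx, drop = FALSE]
    colnames(Xb) <- make.unique(colnames(Xb))
    bags[[b]] <- list(
      features = fidx,
      fit = .fit_rf(Xb, yf[idx], p$base_n_estimators, p$base_max_features))
  }
  bags
}

# Discrete SAMME boosting with weighted resampling; the weak learner is a
# random forest with the default parameters.
.fit_adaboost_rf <- function(X, yf, p) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  rounds <- list()
  for (m in seq_len(p$n_estimators)) {
    repeat {
      idx <- sample(n, n, replace = TRUE, prob = w)
      if (nlevels(droplevels(yf[idx])) == 2) break
    }
    fit <- .fit_rf(X[idx, , drop = FALSE], yf[idx],
                   p$base_n_estimators, p$base_max_features)
    pred <- stats::predict(fit, X)
    miss <- pred != yf
    err <- sum(w[miss])
    if (err >= 0.5) { if (length(rounds) == 0) rounds <- list(list(fit = fit, alpha = 1)); break }
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err)
    rounds[[length(rounds) + 1]] <- list(fit = fit, alpha = alpha)
    if (err < 1e-10) break
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  rounds
}

#' @export
#' @param object a fitted `neckpose_model`.
#' @param newdata numeric matrix with the training feature columns.
#' @param type `"prob"` for the probability of case, `"class"` for labels.
#' @param ... unused.
#' @rdname fit_model
predict.neckpose_model <- function(object, newdata,
                                   type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)[, object$features, drop = FALSE]
  pr <- switch(object$family,
    random_forest = stats::predict(object$fit, X, type = "prob")[, "case"],
    logistic_regression =
      as.numeric(stats::predict(object$fit, X, type = "response")),
    gradient_boosted_trees =
      as.numeric(stats::predict(object$fit, xgboost::xgb.DMatrix(X))),
    bagging_rf = {
      probs <- vapply(object$fit, function(bag) {
        Xb <- X[, bag$features, drop = FALSE]
        colnames(Xb) <- make.unique(colnames(Xb))
        stats::predict(bag$fit, Xb, type = "prob")[, "case"]
      }, numeric(nrow(X)))
      rowMeans(matrix(probs, nrow = nrow(X)))
    },
    adaboost_rf = {
      a <- vapply(object$fit, `[[`, numeric(1), "alpha")
      votes <- vapply(object$fit, function(r)
        as.numeric(stats::predict(r$fit, X) == "case"), numeric(nrow(X)))
      as.numeric(matrix(votes, nrow = nrow(X)) %*% a / sum(a))
    })
  names(pr) <- rownames(newdata)
  if (type == "prob") pr else
    factor(ifelse(pr >= 0.5, "case", "control"),
           levels = c("control", "case"))
}

#' @export
print.neckpose_model <- function(x, ...) {
  cat("<neckpose_model>", x$family, "fitted on",
      length(x$features), "features\n")
  invisible(x)
}
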