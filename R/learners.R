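#' Specify a base learner for bagged PU classification
#'
#' Five families are supported, mirroring the classifiers commonly benchmarked
#' for this task: a random forest, a radial-kernel SVM, a feed-forward neural
#' network with a single hidden layer, a gradient-boosted ensemble with the
#' AdaBoost exponential loss, and a CART decision tree. Hyperparameter names
#' are validated against the family.
#'
#' @param family One of `"random_forest"`, `"svm_rbf"`,
#'   `"feedforward_nn_1hidden"`, `"gbm_adaboost_exponential"`,
#'   `"decision_tree"`.
#' @param ... Named hyperparameters overriding the family defaults:
#'   random forest `n_trees`, `n_features`; SVM `gamma`, `cost`; neural net
#'   `size`, `decay` (plus `maxit`); boosting `n_trees`,
#'   `interaction_depth`; decision tree `maxdepth`, `cp`, `minsplit`.
#' @return An object of class `base_learner`.
#' @export
base_learner <- function(family = c("random_forest", "svm_rbf",
                                    "feedforward_nn_1hidden",
                                    "gbm_adaboost_exponential",
                                    "decision_tree"),
                         ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    random_forest = list(n_trees = 500, n_features = 2),
    svm_rbf = list(gamma = 1, cost = 1),
    feedforward_nn_1hidden = list(size = 3, decay = 0.01, maxit = 200),
    gbm_adaboost_exponential = list(n_trees = 100, interaction_depth = 1),
    decision_tree = list(maxdepth = 30, cp = 0.01, minsplit = 20)
  )
  hp <- list(...)
  bad <- setdiff(names(hp), names(defaults))
  if (length(bad))
    stopf("unknown hyperparameter(s) for %s: %s", family,
          paste(bad, collapse = ", "))
  defaults[names(hp)] <- hp
  structure(list(family = family, hyperparameters = defaults),
            class = "base_learner")
}

#' @export
print.base_learner <- function(x, ...) {
  cat("Base learner:", x$family, "\n  ",
      paste(names(x$hyperparameters), unlist(x$hyperparameters),
            sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Default hyperparameter tuning grid for a learner family
#'
#' @param family Learner family name as in [base_learner()].
#' @return List of named hyperparameter lists (one per grid point).
#' @export
default_tuning_grid <- function(family) {
  grid_from <- function(...) {
    g <- expand.grid(..., KEEP.OUT.ATTRS = FALSE)
    lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
  }
  switch(family,
    random_forest = grid_from(n_trees = c(250, 500, 1000), n_features = 1:3),
    feedforward_nn_1hidden = grid_from(size = c(1, 3, 5, 8),
                                       decay = c(0, 0.01, 0.1)),
    svm_rbf = grid_from(gamma = c(0.1, 0.5, 1, 2), cost = c(0.5, 1, 2, 4)),
    gbm_adaboost_exponential = grid_from(n_trees = c(100, 300, 1000),
                                         interaction_depth = 1:3),
    decision_tree = grid_from(maxdepth = c(2, 5, 30), cp = c(0.001, 0.01)),
    stopf("unknown learner family: %s", family)
  )
}

## --- internal fit / predict dispatch ------------------------------------

prepare_x <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (any(!is.finite(x))) stopf("non-finite feature values")
  x
}

fit_base <- function(spec, x, y) {
  hp <- spec$hyperparameters
  yf <- factor(y, levels = c(0L, 1L))
  if (nlevels(droplevels(yf)) < 2) stopf("training data contains a single class")
  fit <- switch(spec$family,
    random_forest = randomForest::randomForest(
      x, yf, ntree = hp$n_trees,
      mtry = min(hp$n_features, ncol(x))),
    svm_rbf = e1071::svm(
      x, yf, kernel = "radial", gamma = hp$gamma, cost = hp$cost,
      probability = TRUE),
    feedforward_nn_1hidden = nnet::nnet(
      x, y, size = hp$size, decay = hp$decay, maxit = hp$maxit,
      entropy = TRUE, trace = FALSE),
    gbm_adaboost_exponential = fit_adaboost(
      x, y, n_trees = hp$n_trees, maxdepth = hp$interaction_depth),
    decision_tree = {
      df <- data.frame(.y = yf, x, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = hp$maxdepth, cp = hp$cp,
                     minsplit = hp$minsplit, xval = 0))
    }
  )
  structure(list(family = spec$family, fit = fit,
                 feature_names = colnames(x)),
            class = "pu_base_fit")
}

predict_base_prob <- function(model, x) {
  x <- x[, model$feature_names, drop = FALSE]
  switch(model$family,
    random_forest = unname(predict(model$fit, x, type = "prob")[, "1"]),
    svm_rbf = {
      p <- predict(model$fit, x, probability = TRUE)
      unname(attr(p, "probabilities")[, "1"])
    },
    feedforward_nn_1hidden = as.numeric(predict(model$fit, x)),
    gbm_adaboost_exponential = predict_adaboost(model$fit, x),
    decision_tree = {
      df <- data.frame(x, check.names = FALSE)
      unname(predict(model$fit, df, type = "prob")[, "1"])
    }
  )
}

## Discrete AdaBoost.M1 over rpart trees: stagewise minimisation of the
## exponential loss. Depth-limited trees play the role of the weak learner;
## interaction_depth = 1 gives classic decision stumps.
fit_adaboost <- function(x, y, n_trees, maxdepth) {
  y_pm <- ifelse(y == 1L, 1, -1)
  n <- length(y_pm)
  w <- rep(1 / n, n)
  df <- data.frame(.y = factor(y, levels = c(0L, 1L)), x, check.names = FALSE)
  ctrl <- rpart::rpart.control(maxdepth = maxdepth, cp = -1, minsplit = 2,
                               minbucket = 1, xval = 0, maxcompete = 0,
                               maxsurrogate = 0)
  trees <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_trees)) {
    tree <- rpart::rpart(.y ~ ., data = df, weights = w,
                         method = "class", control = ctrl)
    h <- ifelse(predict(tree, df, type = "class") == "1", 1, -1)
    err <- sum(w[h != y_pm])
    if (err >= 0.5) {           # weak learner no better than chance: stop
      if (!length(trees)) { trees <- list(tree); alphas <- 0 }
      break
    }
    alpha <- 0.5 * log((1 - max(err, 1e-10)) / max(err, 1e-10))
    trees[[length(trees) + 1L]] <- tree
    alphas <- c(alphas, alpha)
    if (err <= 1e-10) break     # perfect separation
    w <- w * exp(-alpha * y_pm * h)
    w <- w / sum(w)
  }
  list(trees = trees, alphas = alphas, feature_names = colnames(x))
}

predict_adaboost <- function(model, x) {
  df <- data.frame(x, check.names = FALSE)
  f <- rep(0, nrow(df))
  for (i in seq_along(model$trees)) {
    h <- ifelse(predict(model$trees[[i]], df, type = "class") == "1", 1, -1)
    f <- f + model$alphas[i] * h
  }
  1 / (1 + exp(-2 * f))         # logistic link of the boosted margin
}
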