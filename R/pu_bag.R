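#' Fit a bagged positive-unlabelled classifier
#'
#' Fits an ensemble of base classifiers on bootstrap resamples of the
#' training data, treating unlabelled observations as the negative class
#' (the positive-unlabelled device). Bagging counters the classifier
#' instability caused by hidden positives inside the "negative" class: each
#' bag is a with-replacement resample of size n of the n training rows, a
#' base model is fitted independently on each, and predictions are combined
#' by mean probability (default) or majority vote. Random forests keep their
#' built-in bagging, so `n_bags` is forced to 1 and the single forest is
#' fitted on the full training set.
#'
#' @param x Numeric feature matrix or data frame (rows = observations).
#' @param y Labels: 1 = positive (known target), 0 = unlabelled, as integer,
#'   numeric or factor.
#' @param learner A [base_learner()] specification.
#' @param n_bags Number of bootstrap bags (default 100).
#' @param aggregate Prediction aggregation: `"mean_prob"` averages per-bag
#'   positive-class probabilities, `"vote"` takes the fraction of bags voting
#'   positive at 0.5. Exact ties at the classification threshold resolve to
#'   the non-target class.
#' @param bootstrap If `FALSE`, every bag is the identity resample (all
#'   training rows once); with `n_bags = 1` this reduces the ensemble to the
#'   plain base learner.
#' @param seed Integer seed making bag draws and stochastic learners
#'   reproducible; `NULL` uses the current RNG state.
#' @return An object of class `pu_bag` with `print`, `summary` and `predict`
#'   methods.
#' @seealso [predict.pu_bag()], [nested_cv()], [benchmark_classifiers()]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), ncol = 2)
#' y <- as.integer(x[, 1] + x[, 2] + rnorm(100, sd = 0.3) > 0)
#' fit <- pu_bag(x, y, base_learner("decision_tree"), n_bags = 10, seed = 1)
#' head(predict(fit, x))
#' @export
pu_bag <- function(x, y, learner = base_learner("feedforward_nn_1hidden"),
                   n_bags = 100, aggregate = c("mean_prob", "vote"),
                   bootstrap = TRUE, seed = NULL) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(learner, "base_learner"))
  x <- prepare_x(x)
  y <- as_label(y)
  if (nrow(x) != length(y)) stopf("nrow(x) != length(y)")
  if (length(unique(y)) < 2) stopf("training data contains a single class")
  if (n_bags < 1) stopf("n_bags must be >= 1")
  if (learner$family == "random_forest" && (n_bags != 1 || !bootstrap)) {
    n_bags <- 1L                 # forests bag internally
    bootstrap <- FALSE
  }

  fit_all <- function() {
    n <- nrow(x)
    fits <- vector("list", n_bags)
    bags <- vector("list", n_bags)
    for (b in seq_len(n_bags)) {
      if (bootstrap) {
        for (try in 1:100) {
          idx <- sample.int(n, n, replace = TRUE)
          if (length(unique(y[idx])) == 2) break
        }
      } else {
        idx <- seq_len(n)
      }
      bags[[b]] <- idx
      fits[[b]] <- fit_base(learner, x[idx, , drop = FALSE], y[idx])
    }
    list(fits = fits, bags = bags)
  }
  ens <- if (is.null(seed)) fit_all() else withr::with_seed(as.integer(seed), fit_all())

  structure(list(
    learner = learner,
    fits = ens$fits,
    bag_indices = ens$bags,
    n_bags = as.integer(n_bags),
    aggregate = aggregate,
    bootstrap = bootstrap,
    feature_names = colnames(x),
    n_train = nrow(x),
    class_counts = table(factor(y, levels = c(0L, 1L))),
    seed = seed,
    call = match.call()
  ), class = "pu_bag")
}

#' Predict from a bagged PU classifier
#'
#' @param object A fitted [pu_bag()] model.
#' @param newdata Feature matrix or data frame with the training columns.
#' @param type `"prob"` returns the aggregated positive-class score,
#'   `"class"` the 0/1 class at `threshold`, `"table"` a data frame with
#'   class and both class probabilities (prediction-table layout).
#' @param threshold Classification threshold on the aggregated score; an
#'   observation is called a target only if its score strictly exceeds it,
#'   so exact ties resolve to non-target.
#' @param aggregate Override the aggregation rule chosen at fit time.
#' @param ... Unused.
#' @return Numeric vector, integer vector or data frame according to `type`.
#' @export
predict.pu_bag <- function(object, newdata, type = c("prob", "class", "table"),
                           threshold = 0.5, aggregate = NULL, ...) {
  type <- match.arg(type)
  x <- prepare_x(newdata)
  missing_cols <- setdiff(object$feature_names, colnames(x))
  if (length(missing_cols))
    stopf("newdata lacks training feature column(s): %s",
          paste(missing_cols, collapse = ", "))
  x <- x[, object$feature_names, drop = FALSE]
  agg <- if (is.null(aggregate)) object$aggregate else
    match.arg(aggregate, c("mean_prob", "vote"))
  probs <- vapply(object$fits, predict_base_prob, numeric(nrow(x)), x = x)
  probs <- matrix(probs, nrow = nrow(x))
  score <- if (agg == "mean_prob") rowMeans(probs) else rowMeans(probs > 0.5)
  cls <- as.integer(score > threshold)
  switch(type,
    prob = score,
    class = cls,
    table = data.frame(class = cls, prob_target = score,
                       prob_nontarget = 1 - score))
}

#' @export
print.pu_bag <- function(x, ...) {
  cat("Bagged PU classifier\n")
  cat("  base learner :", x$learner$family, "\n")
  cat("  bags         :", x$n_bags,
      if (!x$bootstrap) "(no bootstrap resampling)", "\n")
  cat("  aggregation  :", x$aggregate, "\n")
  cat("  training set :", x$n_train, "observations (",
      x$class_counts[["1"]], "positive /", x$class_counts[["0"]],
      "unlabelled )\n")
  invisible(x)
}

#' @export
summary.pu_bag <- function(object, ...) {
  hp <- object$learner$hyperparameters
  out <- list(
    family = object$learner$family,
    hyperparameters = hp,
    n_bags = object$n_bags,
    aggregate = object$aggregate,
    n_train = object$n_train,
    class_counts = object$class_counts
  )
  class(out) <- "summary.pu_bag"
  out
}

#' @export
print.summary.pu_bag <- function(x, ...) {
  cat("Bagged PU classifier (", x$family, ")\n", sep = "")
  cat("  hyperparameters:",
      paste(names(x$hyperparameters), unlist(x$hyperparameters),
            sep = " = ", collapse = ", "), "\n")
  cat("  bags:", x$n_bags, " aggregation:", x$aggregate, "\n")
  cat("  training observations:", x$n_train, "\n")
  invisible(x)
}

#' Serialise / restore a bagged model archive
#'
#' Writes the fitted ensemble together with its configuration, seed and
#' feature column order to a single RDS archive.
#'
#' @param model A `pu_bag` object.
#' @param path Archive file path.
#' @return `path` invisibly (save) / the restored model (load).
#' @export
save_pu_bag <- function(model, path) {
  stopifnot(inherits(model, "pu_bag"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_pu_bag
#' @export
load_pu_bag <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pu_bag")) stopf("%s is not a pu_bag archive", path)
  model
}
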