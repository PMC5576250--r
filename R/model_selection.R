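#' Nested cross-validation configuration
#'
#' @param k_outer,k_inner Outer and inner fold counts (default fourfold each:
#'   the inner loop tunes hyperparameters, the outer loop estimates
#'   performance on data never seen during tuning).
#' @param tuning_grid List of hyperparameter lists to search; `NULL` uses
#'   [default_tuning_grid()] for the learner family.
#' @param tuning_measure Measure minimised by the inner loop (currently
#'   misclassification error).
#' @param seed Integer seed for fold construction and per-fit seeds.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(k_outer = 4, k_inner = 4, tuning_grid = NULL,
                      tuning_measure = "misclassification_error", seed = 1L) {
  if (k_outer < 2 || k_inner < 2) stopf("k_outer and k_inner must be >= 2")
  if (!is.null(tuning_grid) && !length(tuning_grid))
    stopf("tuning_grid must be non-empty")
  structure(list(k_outer = as.integer(k_outer), k_inner = as.integer(k_inner),
                 tuning_grid = tuning_grid, tuning_measure = tuning_measure,
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Stratified k-fold assignment
#'
#' Assigns each observation to exactly one fold; within each class the fold
#' sizes differ by at most one, so balanced classes stay balanced in every
#' fold.
#'
#' @param y 0/1 label vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:k`.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  y <- as_label(y)
  folds <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

eval_fold_metrics <- function(score, truth, threshold = 0.5) {
  cls <- as.integer(score > threshold)
  rep <- confusion_metrics(confusion_matrix(truth, cls))
  auc <- tryCatch(roc_auc(score, truth), error = function(e) NA_real_)
  c(misclassification_error = rep$misclassification_error,
    accuracy = rep$accuracy, auc = auc,
    sensitivity_recall = rep$sensitivity_recall,
    specificity = rep$specificity, precision = rep$precision, f1 = rep$f1)
}

#' Nested cross-validation of a bagged PU classifier
#'
#' For each outer fold, an inner k-fold grid search over the outer-training
#' portion selects the hyperparameter point with the lowest mean
#' misclassification error; a model with that point is refitted on the full
#' outer-training portion and evaluated once on the outer-test portion.
#' Outer-test rows are never seen during tuning. Grid points that fail to
#' fit are skipped with a warning; if every point fails the run aborts.
#' With a single-point grid the inner loop is skipped and the procedure
#' reduces to plain k-fold evaluation.
#'
#' @param learner A [base_learner()]; grid points override its
#'   hyperparameters.
#' @param x Feature matrix (rows = observations, rownames = ids).
#' @param y 0/1 labels.
#' @param config A [cv_config()].
#' @param n_bags,aggregate Passed to [pu_bag()] for every fit.
#' @return List with `per_fold` metrics data frame, `chosen` hyperparameters
#'   per outer fold, `summary` (mean of per-fold metrics), `pooled_confusion`
#'   (outer-fold predictions pooled into one confusion matrix), `predictions`
#'   (per-observation outer-test scores), `outer_folds`, and
#'   `inner_assignments` (per outer fold, the inner-fold ids of the
#'   outer-training rows).
#' @export
nested_cv <- function(learner, x, y, config = cv_config(), n_bags = 100,
                      aggregate = "mean_prob") {
  stopifnot(inherits(learner, "base_learner"), inherits(config, "cv_config"))
  x <- prepare_x(x)
  y <- as_label(y)
  grid <- config$tuning_grid
  if (is.null(grid)) grid <- default_tuning_grid(learner$family)
  outer <- stratified_folds(y, config$k_outer, seed = config$seed)

  per_fold <- vector("list", config$k_outer)
  chosen <- vector("list", config$k_outer)
  inner_assignments <- vector("list", config$k_outer)
  preds <- vector("list", config$k_outer)

  with_hp <- function(g) {
    do.call(base_learner, c(list(family = learner$family),
                            utils::modifyList(learner$hyperparameters, g)))
  }

  for (o in seq_len(config$k_outer)) {
    tr <- which(outer != o)
    te <- which(outer == o)
    if (length(unique(y[tr])) < 2)
      stopf("outer training fold %d contains a single class", o)

    if (length(grid) > 1) {
      inner <- stratified_folds(y[tr], config$k_inner,
                                seed = derive_seed(config$seed, o))
      inner_assignments[[o]] <- stats::setNames(inner, tr)
      grid_err <- vapply(seq_along(grid), function(gi) {
        errs <- vapply(seq_len(config$k_inner), function(j) {
          itr <- tr[inner != j]
          ite <- tr[inner == j]
          fit <- tryCatch(
            pu_bag(x[itr, , drop = FALSE], y[itr], with_hp(grid[[gi]]),
                   n_bags = n_bags, aggregate = aggregate,
                   seed = derive_seed(config$seed, o * 1000 + gi * 10 + j)),
            error = function(e) NULL)
          if (is.null(fit)) return(NA_real_)
          score <- predict(fit, x[ite, , drop = FALSE], type = "prob")
          mean(as.integer(score > 0.5) != y[ite])
        }, numeric(1))
        if (all(is.na(errs))) NA_real_ else mean(errs, na.rm = TRUE)
      }, numeric(1))
      if (all(is.na(grid_err)))
        stopf("all tuning grid points failed to fit in outer fold %d", o)
      if (any(is.na(grid_err)))
        warnf("%d grid point(s) failed to fit in outer fold %d and were skipped",
              sum(is.na(grid_err)), o)
      best <- which.min(grid_err)
    } else {
      best <- 1L
      inner_assignments[[o]] <- stats::setNames(integer(0), character(0))
    }
    chosen[[o]] <- grid[[best]]

    fit <- pu_bag(x[tr, , drop = FALSE], y[tr], with_hp(grid[[best]]),
                  n_bags = n_bags, aggregate = aggregate,
                  seed = derive_seed(config$seed, 90000 + o))
    score <- predict(fit, x[te, , drop = FALSE], type = "prob")
    per_fold[[o]] <- eval_fold_metrics(score, y[te])
    preds[[o]] <- data.frame(
      id = if (is.null(rownames(x))) as.character(te) else rownames(x)[te],
      fold = o, truth = y[te], score = score,
      class = as.integer(score > 0.5), stringsAsFactors = FALSE)
  }

  per_fold <- as.data.frame(do.call(rbind, per_fold))
  per_fold <- cbind(fold = seq_len(config$k_outer), per_fold)
  predictions <- do.call(rbind, preds)
  pooled <- confusion_matrix(predictions$truth, predictions$class)
  list(per_fold = per_fold,
       chosen = chosen,
       summary = colMeans(per_fold[, -1, drop = FALSE]),
       pooled_confusion = pooled,
       predictions = predictions,
       outer_folds = outer,
       inner_assignments = inner_assignments)
}

#' Benchmark several classifier families by nested cross-validation
#'
#' Runs [nested_cv()] for each learner specification and collects the mean
#' outer-fold performance measures into one table (misclassification error,
#' accuracy, AUC, sensitivity/recall, specificity, precision, F1), plus the
#' pooled outer-fold confusion matrix and per-fold details for each family.
#'
#' @param specs Named list of [base_learner()] specifications.
#' @param x,y Features and 0/1 labels.
#' @param config A [cv_config()].
#' @param n_bags,aggregate Passed to [pu_bag()].
#' @return List with `table` (one row per classifier) and `details` (the full
#'   [nested_cv()] result per classifier).
#' @export
benchmark_classifiers <- function(specs, x, y, config = cv_config(),
                                  n_bags = 100, aggregate = "mean_prob") {
  if (!length(specs)) stopf("need at least one learner specification")
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, function(s) s$family, character(1))
  details <- lapply(specs, nested_cv, x = x, y = y, config = config,
                    n_bags = n_bags, aggregate = aggregate)
  tab <- do.call(rbind, lapply(details, function(d)
    as.data.frame(as.list(d$summary))))
  tab <- cbind(classifier = names(specs), tab)
  rownames(tab) <- NULL
  list(table = tab, details = details)
}

#' Monte-Carlo stability of the unlabelled-class sampling
#'
#' Repeatedly redraws the unlabelled half of the working set from the pool
#' of unlabelled genes, rebuilds the stratified train/test split, refits the
#' classifier and evaluates accuracy and AUC on the iteration's test set --
#' quantifying how much performance depends on which unlabelled genes were
#' sampled as the negative class.
#'
#' @param learner A [base_learner()].
#' @param x Feature matrix for all candidate genes (rownames = gene ids).
#' @param y 0/1 labels aligned with `x` (1 = known positive).
#' @param pool_ids Gene ids eligible as unlabelled draws (default: all
#'   label-0 rows).
#' @param n_iterations Number of Monte-Carlo iterations.
#' @param train_fraction Training fraction of each working set.
#' @param n_bags,aggregate Passed to [pu_bag()].
#' @param seed Integer seed; per-iteration seeds are derived from it.
#' @param iteration_seeds Optional explicit per-iteration seeds (overrides
#'   derivation; useful to replay iterations).
#' @return List with `per_iteration` (accuracy and AUC per iteration) and
#'   `summary` (mean and sd of both).
#' @export
monte_carlo_stability <- function(learner, x, y, pool_ids = NULL,
                                  n_iterations = 200, train_fraction = 0.8,
                                  n_bags = 1, aggregate = "mean_prob",
                                  seed = 1L, iteration_seeds = NULL) {
  x <- prepare_x(x)
  y <- as_label(y)
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  if (is.null(pool_ids)) pool_ids <- rownames(x)[y == 0]
  pos_ids <- rownames(x)[y == 1]
  n_pos <- length(pos_ids)
  if (length(pool_ids) < n_pos)
    stopf("unlabelled pool (%d) smaller than positive set (%d)",
          length(pool_ids), n_pos)
  if (n_iterations < 2) stopf("n_iterations must be >= 2")
  if (is.null(iteration_seeds))
    iteration_seeds <- vapply(seq_len(n_iterations), derive_seed,
                              integer(1), seed = seed)

  res <- t(vapply(seq_len(n_iterations), function(i) {
    it_seed <- iteration_seeds[i]
    withr::with_seed(it_seed, {
      unl <- sample(pool_ids, n_pos)
      n_train <- round(train_fraction * n_pos)
      tr_pos <- sample(pos_ids, n_train)
      tr_unl <- sample(unl, n_train)
    })
    tr <- c(tr_pos, tr_unl)
    te <- c(setdiff(pos_ids, tr_pos), setdiff(unl, tr_unl))
    fit <- pu_bag(x[tr, , drop = FALSE], y[match(tr, rownames(x))],
                  learner, n_bags = n_bags, aggregate = aggregate,
                  seed = it_seed)
    score <- predict(fit, x[te, , drop = FALSE], type = "prob")
    truth <- y[match(te, rownames(x))]
    c(accuracy = mean(as.integer(score > 0.5) == truth),
      auc = tryCatch(roc_auc(score, truth), error = function(e) NA_real_))
  }, numeric(2)))

  per_iteration <- data.frame(iteration = seq_len(n_iterations),
                              accuracy = res[, "accuracy"], auc = res[, "auc"])
  list(per_iteration = per_iteration,
       summary = c(mean_accuracy = mean(per_iteration$accuracy),
                   sd_accuracy = stats::sd(per_iteration$accuracy),
                   mean_auc = mean(per_iteration$auc, na.rm = TRUE),
                   sd_auc = stats::sd(per_iteration$auc, na.rm = TRUE)))
}
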