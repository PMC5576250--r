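one_point_grid <- list(list(maxdepth = 5, cp = 0.01, minsplit = 10))

test_that("stratified folds partition each class evenly and exhaustively", {
  y <- c(rep(1L, 41), rep(0L, 43))
  folds <- stratified_folds(y, 4, seed = 2)
  expect_identical(sort(unique(folds)), 1:4)
  expect_identical(length(folds), length(y))
  for (cl in 0:1) {
    sizes <- table(folds[y == cl])
    expect_lte(diff(range(sizes)), 1)
  }
})

test_that("a single-point grid degenerates nested CV to a plain k-fold run with the same folds", {
  cl <- make_clouds(80, seed = 21, sep = 1)
  cfg <- cv_config(tuning_grid = one_point_grid, seed = 6)
  cv <- nested_cv(base_learner("decision_tree"), cl$x, cl$y, cfg, n_bags = 1)

  ## independent direct k-fold evaluation on the same fold assignment
  folds <- stratified_folds(cl$y, 4, seed = 6)
  expect_identical(cv$outer_folds, folds)
  for (o in 1:4) {
    tr <- folds != o
    fit <- pu_bag(cl$x[tr, ], cl$y[tr],
                  base_learner("decision_tree", maxdepth = 5, cp = 0.01,
                               minsplit = 10),
                  n_bags = 1, seed = putarget:::derive_seed(6, 90000 + o))
    score <- predict(fit, cl$x[!tr, ])
    expect_equal(cv$per_fold$accuracy[o],
                 mean(as.integer(score > 0.5) == cl$y[!tr]))
  }
  ## each observation is in exactly one outer test fold
  expect_identical(sort(unique(cv$predictions$id)), sort(rownames(cl$x)))
})

test_that("outer test rows never leak into inner tuning folds", {
  cl <- make_clouds(60, seed = 23, sep = 1)
  cfg <- cv_config(tuning_grid = list(list(maxdepth = 1, cp = -1, minsplit = 2),
                                      list(maxdepth = 4, cp = -1, minsplit = 2)),
                   seed = 4)
  cv <- nested_cv(base_learner("decision_tree"), cl$x, cl$y, cfg, n_bags = 1)
  for (o in 1:4) {
    outer_test <- which(cv$outer_folds == o)
    inner_train_ids <- as.integer(names(cv$inner_assignments[[o]]))
    expect_length(intersect(outer_test, inner_train_ids), 0)
  }
})

test_that("the inner loop recovers a planted dominant hyperparameter on XOR data", {
  xo <- make_xor(200, seed = 3)
  cfg <- cv_config(tuning_grid = list(list(maxdepth = 1, cp = -1, minsplit = 2),
                                      list(maxdepth = 5, cp = -1, minsplit = 2)),
                   seed = 5)
  cv <- nested_cv(base_learner("decision_tree"), xo$x, xo$y, cfg, n_bags = 1)
  chosen_depths <- vapply(cv$chosen, function(g) g$maxdepth, numeric(1))
  expect_gte(sum(chosen_depths == 5), 3)
})

test_that("summary metrics are exact fold means and pooled confusion conserves class counts", {
  cl <- make_clouds(80, seed = 25, sep = 1)
  cv <- nested_cv(base_learner("decision_tree"), cl$x, cl$y,
                  cv_config(tuning_grid = one_point_grid, seed = 8), n_bags = 1)
  expect_equal(unname(cv$summary),
               unname(colMeans(cv$per_fold[, -1])), tolerance = 1e-12)
  cm <- cv$pooled_confusion
  expect_identical(unname(cm["tn"] + cm["fp"]), sum(cl$y == 0))
  expect_identical(unname(cm["fn"] + cm["tp"]), sum(cl$y == 1))
})

test_that("benchmarking reports near-perfect accuracy for all families on separable data", {
  cl <- make_clouds(80, seed = 27)
  specs <- list(
    rf = base_learner("random_forest", n_trees = 100),
    nn = base_learner("feedforward_nn_1hidden", size = 2),
    svm = base_learner("svm_rbf"),
    gbm = base_learner("gbm_adaboost_exponential", n_trees = 20),
    tree = base_learner("decision_tree"))
  cfg <- cv_config(tuning_grid = list(list()), seed = 9)
  b <- benchmark_classifiers(specs, cl$x, cl$y, cfg, n_bags = 2)
  expect_identical(b$table$classifier, names(specs))
  expect_true(all(b$table$accuracy >= 0.9))
  expect_identical(
    names(b$table),
    c("classifier", "misclassification_error", "accuracy", "auc",
      "sensitivity_recall", "specificity", "precision", "f1"))
})

test_that("permuted labels drive benchmark AUC to chance", {
  aucs <- vapply(1:10, function(r) {
    cl <- make_clouds(200, seed = 30 + r, sep = 1.5)
    y_perm <- withr::with_seed(r, sample(cl$y))
    cv <- nested_cv(base_learner("decision_tree"), cl$x, y_perm,
                    cv_config(tuning_grid = one_point_grid, seed = r),
                    n_bags = 1)
    unname(cv$summary["auc"])
  }, numeric(1))
  expect_true(all(aucs >= 0.4 & aucs <= 0.6))
})

test_that("outer-CV accuracy agrees with held-out test accuracy (no overfitting)", {
  d <- make_pu_data(strong_config(n_genes = 3000,
                                  true_target_fraction = 0.15, seed = 31))
  cv <- nested_cv(base_learner("decision_tree"),
                  part_x(d, "train"), part_y(d, "train"),
                  cv_config(tuning_grid = one_point_grid, seed = 7), n_bags = 1)
  fit <- pu_bag(part_x(d, "train"), part_y(d, "train"),
                base_learner("decision_tree", maxdepth = 5, cp = 0.01,
                             minsplit = 10),
                n_bags = 1, bootstrap = FALSE, seed = 1)
  te <- evaluate_on_test(fit, part_x(d, "test"), part_y(d, "test"))
  expect_lt(abs(unname(cv$summary["accuracy"]) - te$accuracy), 0.05)
})

test_that("Monte-Carlo stability: identical iteration seeds give identical metrics", {
  d <- make_pu_data(strong_config(n_genes = 600, seed = 33))
  working <- d$partition$partition != "prediction"
  mc <- monte_carlo_stability(
    base_learner("decision_tree"), d$features, d$partition$label,
    n_iterations = 2, n_bags = 1, iteration_seeds = c(7L, 7L))
  expect_identical(mc$per_iteration$accuracy[1], mc$per_iteration$accuracy[2])
  expect_identical(unname(mc$summary["sd_accuracy"]), 0)
})

test_that("Monte-Carlo stability concentrates under strong signal and is at chance under none", {
  d <- make_pu_data(strong_config(n_genes = 1200, seed = 35))
  mc <- monte_carlo_stability(base_learner("decision_tree"),
                              d$features, d$partition$label,
                              n_iterations = 50, n_bags = 1, seed = 2)
  expect_lt(unname(mc$summary["sd_accuracy"]), 0.1)

  d0 <- make_pu_data(null_config(n_genes = 500, seed = 37))
  mc0 <- monte_carlo_stability(base_learner("decision_tree"),
                               d0$features, d0$partition$label,
                               n_iterations = 50, n_bags = 1, seed = 3)
  expect_lt(abs(unname(mc0$summary["mean_auc"]) - 0.5), 0.05)
})
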