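test_that("confusion metrics handle perfect classifiers and undefined denominators", {
  perfect <- confusion_metrics(tn = 10, fp = 0, fn = 0, tp = 10)
  for (m in c("accuracy", "sensitivity_recall", "specificity", "precision",
              "f1"))
    expect_equal(perfect[[m]], 1)
  expect_equal(perfect$misclassification_error, 0)

  ## no predicted positives: precision undefined, reported NA not 0
  none <- confusion_metrics(tn = 10, fp = 0, fn = 5, tp = 0)
  expect_true(is.na(none$precision))
  expect_true(is.na(none$f1))
  expect_equal(none$sensitivity_recall, 0)
  expect_error(confusion_metrics(0, 0, 0, 0), "empty")
  expect_error(confusion_metrics(-1, 0, 0, 2), "non-negative")
  ## complementarity holds to machine precision
  r <- confusion_metrics(tn = 3, fp = 4, fn = 5, tp = 6)
  expect_equal(r$accuracy + r$misclassification_error, 1, tolerance = 1e-12)
  expect_true(r$f1 >= min(r$precision, r$sensitivity_recall) &&
              r$f1 <= max(r$precision, r$sensitivity_recall))
})

test_that("AUC equals the exhaustive pairwise U-statistic, with midranked ties", {
  scores <- c(0.9, 0.8, 0.8, 0.6, 0.5, 0.4, 0.3, 0.1)
  labels <- c(1, 1, 0, 1, 0, 1, 0, 0)
  ## brute-force pairwise comparison oracle
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (n in neg)
    wins <- wins + (p > n) + 0.5 * (p == n)
  expect_equal(roc_auc(scores, labels), wins / (length(pos) * length(neg)))

  expect_equal(roc_auc(c(3, 2, 1, 0), c(1, 1, 0, 0)), 1)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC is invariant to strictly monotone score transforms and matches an independent implementation", {
  set.seed(41)
  scores <- runif(200)
  labels <- as.integer(runif(200) < plogis(4 * scores - 2))
  a <- roc_auc(scores, labels)
  expect_equal(roc_auc(qlogis(pmin(pmax(scores, 1e-6), 1 - 1e-6)), labels), a)
  expect_equal(roc_auc(scores^3, labels), a)
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                 quiet = TRUE))))

  ## labels independent of scores: chance-level AUC
  set.seed(43)
  s <- runif(500); l <- rep(0:1, 250)
  expect_lt(abs(roc_auc(s, l) - 0.5), 0.06)
})

test_that("precision-recall points equal a brute-force per-threshold recount", {
  scores <- c(0.9, 0.7, 0.7, 0.4, 0.2)
  labels <- c(1, 1, 0, 0, 1)
  pr <- pr_curve(scores, labels)
  for (i in seq_len(nrow(pr))) {
    pred <- scores >= pr$threshold[i]
    tp <- sum(pred & labels == 1)
    expect_equal(pr$recall[i], tp / 3)
    expect_equal(pr$precision[i], tp / sum(pred))
  }
  ## recall is non-increasing as the threshold rises
  expect_true(all(diff(pr$recall[order(pr$threshold)]) <= 0))
  ## perfect ranking: every recall level, including 1, is reached at precision 1
  prp <- pr_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  for (r in unique(prp$recall))
    expect_equal(max(prp$precision[prp$recall == r]), 1)
  ## uninformative scores: precision near prevalence at full recall
  set.seed(47)
  s <- runif(1000); l <- as.integer(runif(1000) < 0.3)
  prn <- pr_curve(s, l)
  expect_lt(abs(prn$precision[which.max(prn$recall)] - mean(l)), 0.05)
})

test_that("ROC curve endpoints and monotonicity are correct", {
  set.seed(49)
  s <- runif(100); l <- rep(0:1, 50)
  rc <- roc_curve(s, l)
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
})

test_that("held-out evaluation is internally consistent and refuses leaked rows", {
  cl <- make_clouds(100, seed = 51)
  tr <- seq_len(60); te <- 61:100
  fit <- pu_bag(cl$x[tr, ], cl$y[tr], base_learner("decision_tree"),
                n_bags = 2, seed = 1)
  rep <- evaluate_on_test(fit, cl$x[te, ], cl$y[te],
                          train_ids = rownames(cl$x)[tr])
  again <- confusion_metrics(rep$confusion)
  expect_equal(rep$accuracy, again$accuracy)
  expect_equal(rep$precision, again$precision)
  ## threshold 1 forces all-negative predictions
  allneg <- evaluate_on_test(fit, cl$x[te, ], cl$y[te], threshold = 1)
  expect_equal(allneg$sensitivity_recall, 0)
  expect_equal(allneg$specificity, 1)
  expect_error(
    evaluate_on_test(fit, cl$x[tr[1:5], ], cl$y[tr[1:5]],
                     train_ids = rownames(cl$x)[tr]),
    "overlaps")
})

test_that("stage association recovers a planted stage effect and is quiet under the null", {
  stages <- rep(c("Preclinical", "Phase II Clinical Trial", "Launched"),
                length.out = 400)
  ## planted: Launched genes predicted correctly at 0.9 vs 0.5 elsewhere
  hits <- vapply(1:50, function(r) {
    withr::with_seed(500 + r, {
      p_correct <- ifelse(stages == "Launched", 0.9, 0.5)
      correct <- as.integer(runif(400) < p_correct)
    })
    res <- stage_association(correct, stages)
    res$p_value[res$stage == "Launched"] < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  ## identical rates: significant calls stay near the nominal rate
  null_p <- unlist(lapply(1:20, function(r) {
    withr::with_seed(600 + r,
      correct <- as.integer(runif(300) < 0.6))
    stage_association(correct, stages[1:300])$p_value
  }))
  expect_lte(mean(null_p < 0.05), 0.15)

  expect_error(stage_association(c(1, 0), c("Launched", "Launched")),
               ">= 2 distinct stages")
})
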