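#' Confusion matrix and derived performance measures
#'
#' `confusion_matrix()` tabulates actual vs predicted 0/1 classes;
#' `confusion_metrics()` derives the standard performance measures from the
#' four cells. Metrics with a zero denominator are reported as `NA`
#' (undefined), never as 0.
#'
#' @param truth,predicted 0/1 vectors of actual and predicted classes.
#' @param tn,fp,fn,tp Cell counts (actual x predicted).
#' @return `confusion_matrix()`: an object of class `confusion_matrix` (named
#'   count vector). `confusion_metrics()`: a `metrics_report` list with
#'   `misclassification_error`, `accuracy`, `sensitivity_recall`,
#'   `specificity`, `precision`, `f1`.
#' @examples
#' cm <- confusion_matrix_counts(tn = 229, fp = 63, fn = 100, tp = 176)
#' confusion_metrics(cm)
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- as_label(truth)
  predicted <- as_label(predicted)
  stopifnot(length(truth) == length(predicted))
  confusion_matrix_counts(
    tn = sum(truth == 0 & predicted == 0),
    fp = sum(truth == 0 & predicted == 1),
    fn = sum(truth == 1 & predicted == 0),
    tp = sum(truth == 1 & predicted == 1))
}

#' @rdname confusion_matrix
#' @export
confusion_matrix_counts <- function(tn, fp, fn, tp) {
  counts <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("confusion matrix cells must be non-negative integers")
  structure(as.integer(counts), names = names(counts),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x["tn"], x["fp"], x["fn"], x["tp"]), nrow = 2, byrow = TRUE,
              dimnames = list(c("Actual: non-target", "Actual: target"),
                              c("Predicted: non-target", "Predicted: target")))
  m <- cbind(m, Sum = rowSums(m))
  m <- rbind(m, Sum = colSums(m))
  print(m)
  invisible(x)
}

#' @rdname confusion_matrix
#' @export
confusion_metrics <- function(tn, fp = NULL, fn = NULL, tp = NULL) {
  if (inherits(tn, "confusion_matrix")) {
    cm <- tn
  } else {
    cm <- confusion_matrix_counts(tn, fp, fn, tp)
  }
  total <- sum(cm)
  if (total == 0) stopf("empty confusion matrix")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  acc <- safe_div(cm["tp"] + cm["tn"], total)
  sens <- safe_div(cm["tp"], cm["tp"] + cm["fn"])
  spec <- safe_div(cm["tn"], cm["tn"] + cm["fp"])
  prec <- safe_div(cm["tp"], cm["tp"] + cm["fp"])
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  structure(list(
    misclassification_error = unname(1 - acc),
    accuracy = unname(acc),
    sensitivity_recall = unname(sens),
    specificity = unname(spec),
    precision = unname(prec),
    f1 = unname(f1),
    confusion = cm
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  vals <- unlist(x[c("misclassification_error", "accuracy", "auc",
                     "sensitivity_recall", "specificity", "precision", "f1")])
  vals <- vals[!is.na(names(vals))]
  cat(paste(format(names(vals), width = 24),
            formatC(vals, format = "f", digits = digits),
            collapse = "\n"), "\n")
  invisible(x)
}

#' ROC curve and area under the curve
#'
#' The AUC is computed as the midrank Mann-Whitney U statistic normalised by
#' n1 * n0 -- the probability that a random positive outranks a random
#' negative, with ties counted half -- which equals trapezoidal integration
#' of the ROC curve over all score thresholds.
#'
#' @param scores Numeric classification scores (higher = more target-like).
#' @param labels 0/1 labels.
#' @return `roc_auc()`: the AUC as a single number. `roc_curve()`: a data
#'   frame of `threshold`, `fpr`, `tpr` points over all distinct thresholds.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_label(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname roc_auc
#' @export
roc_curve <- function(scores, labels) {
  labels <- as_label(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & labels == 0) / n0, tpr = sum(pred & labels == 1) / n1)
  }, numeric(2)))
  data.frame(threshold = thr, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
}

#' Precision-recall curve
#'
#' Precision and recall at every distinct score threshold (classification
#' rule: score >= threshold).
#'
#' @inheritParams roc_auc
#' @return Data frame of `threshold`, `recall`, `precision` points.
#' @export
pr_curve <- function(scores, labels) {
  labels <- as_label(labels)
  n1 <- sum(labels == 1)
  if (n1 == 0) stopf("no positive labels")
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(thr, function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    c(recall = tp / n1,
      precision = if (sum(pred) == 0) NA_real_ else tp / sum(pred))
  }, numeric(2)))
  data.frame(threshold = thr, recall = pts[, "recall"],
             precision = pts[, "precision"])
}

#' Evaluate a fitted model on a held-out test partition
#'
#' Asserts that the test rows are disjoint from the rows the model was
#' trained on (by gene id) and computes the full metrics report including
#' AUC plus the confusion matrix.
#'
#' @param model A fitted [pu_bag()] model.
#' @param x_test Feature matrix of the held-out rows (gene rownames).
#' @param y_test 0/1 labels of the held-out rows.
#' @param train_ids Optional character vector of training gene ids; if the
#'   test rownames intersect it, evaluation aborts.
#' @param threshold Classification threshold.
#' @return A `metrics_report` with an `auc` element and the confusion matrix.
#' @export
evaluate_on_test <- function(model, x_test, y_test, train_ids = NULL,
                             threshold = 0.5) {
  if (!is.null(train_ids) && !is.null(rownames(x_test))) {
    overlap <- intersect(rownames(x_test), train_ids)
    if (length(overlap))
      stopf("test set overlaps training set (%d gene(s), e.g. %s)",
            length(overlap), overlap[1])
  }
  y_test <- as_label(y_test)
  score <- predict(model, x_test, type = "prob")
  cls <- as.integer(score > threshold)
  rep <- confusion_metrics(confusion_matrix(y_test, cls))
  rep$auc <- roc_auc(score, y_test)
  rep$scores <- score
  rep
}

#' Stage-wise association of correct target prediction
#'
#' Logistic regression of a correct-prediction indicator on development
#' stage, testing whether genes at more advanced pipeline stages are easier
#' to recognise. Returns the Wald coefficient and two-sided p-value per
#' stage against the reference level; under quasi-separation the Wald p is
#' replaced by a likelihood-ratio p and flagged.
#'
#' @param correct 0/1 indicator (e.g. label-1 gene predicted 1 at 0.5).
#' @param stage Character/factor vector of stages, same length.
#' @param reference Reference stage level (default `"Preclinical"`).
#' @return Data frame with `stage`, `estimate`, `p_value`, `separation`.
#' @export
stage_association <- function(correct, stage, reference = "Preclinical") {
  correct <- as_label(correct)
  stage <- as.character(stage)
  stopifnot(length(correct) == length(stage))
  lev <- unique(stage)
  if (length(lev) < 2) stopf("need >= 2 distinct stages, got %d", length(lev))
  if (reference %in% lev) lev <- c(reference, setdiff(lev, reference))
  f <- factor(stage, levels = lev)
  fit <- stats::glm(correct ~ f, family = stats::binomial())
  co <- summary(fit)$coefficients
  idx <- grep("^f", rownames(co))
  est <- co[idx, "Estimate"]
  p <- co[idx, "Pr(>|z|)"]
  sep <- abs(est) > 10 | co[idx, "Std. Error"] > 100
  if (any(sep)) {
    ## likelihood-ratio fallback per separated stage: drop its rows' stage
    ## contrast by refitting without that level collapsed is awkward; use the
    ## overall LRT of the stage factor as the reported p for flagged stages
    lrt <- stats::anova(stats::glm(correct ~ 1, family = stats::binomial()),
                        fit, test = "LRT")
    p[sep] <- lrt$`Pr(>Chi)`[2]
  }
  data.frame(stage = sub("^f", "", rownames(co)[idx]),
             estimate = unname(est), p_value = unname(p),
             separation = unname(sep), stringsAsFactors = FALSE,
             row.names = NULL)
}
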