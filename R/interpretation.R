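#' Feature importance by chi-squared test and information gain
#'
#' Each continuous feature is discretised into equal-frequency bins with all
#' zeros collapsed into a single bin (the matrix is dominated by zeros, so
#' quantile bins on the raw values would degenerate). Importance is then the
#' chi-squared statistic of the bin-by-label contingency table and the
#' information gain H(label) - H(label | bin) in bits (base-2). No feature
#' is removed; the scores are purely descriptive.
#'
#' @param x Feature matrix.
#' @param y 0/1 labels.
#' @param method `"both"` (default), `"chisq"` or `"infogain"`.
#' @param n_bins Total number of bins per feature (>= 2); one bin holds the
#'   zeros, the nonzero values are cut into `n_bins - 1` equal-frequency bins.
#' @return Data frame with one row per feature: `feature`, `chi_squared`,
#'   `information_gain` (columns according to `method`), plus attribute
#'   `n_bins`. Constant features get importance 0 with a warning.
#' @export
feature_importance <- function(x, y, method = c("both", "chisq", "infogain"),
                               n_bins = 5) {
  method <- match.arg(method)
  x <- prepare_x(x)
  y <- as_label(y)
  if (n_bins < 2) stopf("n_bins must be >= 2")

  entropy <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log2(p))
  }
  h_label <- entropy(table(y))

  bin_feature <- function(v) {
    b <- integer(length(v))          # bin 0 = zeros
    nz <- v != 0
    if (any(nz)) {
      qs <- unique(stats::quantile(v[nz], probs = seq(0, 1,
                                                      length.out = n_bins),
                                   names = FALSE))
      if (length(qs) < 2) {
        b[nz] <- 1L
      } else {
        b[nz] <- as.integer(cut(v[nz], breaks = qs, include.lowest = TRUE))
      }
    }
    b
  }

  rows <- lapply(colnames(x), function(f) {
    v <- x[, f]
    if (length(unique(v)) < 2) {
      warnf("feature '%s' is constant; importance set to 0", f)
      return(data.frame(feature = f, chi_squared = 0, information_gain = 0))
    }
    bins <- bin_feature(v)
    tab <- table(bins, y)
    chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
    h_cond <- sum(rowSums(tab) / sum(tab) * apply(tab, 1, entropy))
    data.frame(feature = f, chi_squared = unname(chi),
               information_gain = h_label - h_cond)
  })
  out <- do.call(rbind, rows)
  out$information_gain <- pmax(out$information_gain, 0)
  if (method == "chisq") out$information_gain <- NULL
  if (method == "infogain") out$chi_squared <- NULL
  attr(out, "n_bins") <- n_bins
  attr(out, "label_entropy") <- h_label
  out
}

#' Fit and report an inspection decision tree
#'
#' Fits a CART classification tree on the supplied (training) data and
#' extracts a node-by-node report of the classification criteria: split
#' variable and threshold, predicted class, per-class observation counts and
#' the percentage of observations reaching each node. Degenerate data yields
#' a single-node tree with a warning.
#'
#' @param x Feature matrix.
#' @param y 0/1 labels.
#' @param control An [rpart::rpart.control()] for the fit.
#' @return A list of class `tree_report` with elements `nodes` (data frame:
#'   `node`, `depth`, `is_leaf`, `split`, `predicted_class`, `n_nontarget`,
#'   `n_target`, `percent`) and `fit` (the underlying rpart object).
#' @export
fit_inspection_tree <- function(x, y, control = rpart::rpart.control(xval = 0)) {
  x <- prepare_x(x)
  y <- as_label(y)
  if (length(unique(y)) < 2) stopf("both classes must be present")
  df <- data.frame(.y = factor(y, levels = c(0L, 1L)), x, check.names = FALSE)
  fit <- rpart::rpart(.y ~ ., data = df, method = "class", control = control)
  frame <- fit$frame
  if (nrow(frame) == 1)
    warnf("degenerate data: inspection tree has a single node")
  node_ids <- as.integer(rownames(frame))
  labs <- labels(fit)
  nodes <- data.frame(
    node = node_ids,
    depth = floor(log2(node_ids)),
    is_leaf = frame$var == "<leaf>",
    split = ifelse(frame$var == "<leaf>", NA_character_,
                   as.character(frame$var)),
    rule = labs,
    predicted_class = as.integer(frame$yval) - 1L,
    n_nontarget = frame$yval2[, 2],
    n_target = frame$yval2[, 3],
    percent = 100 * frame$n / frame$n[1],
    stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, fit = fit), class = "tree_report")
}

#' @export
print.tree_report <- function(x, ...) {
  n <- x$nodes
  for (i in seq_len(nrow(n))) {
    indent <- strrep("  ", n$depth[i])
    cat(sprintf("%s[%d] %s  class=%d  n=(%d,%d)  %.1f%%\n",
                indent, n$node[i],
                if (is.na(n$split[i])) paste0("leaf (", n$rule[i], ")")
                else paste0(n$rule[i], " -> split on ", n$split[i]),
                n$predicted_class[i], n$n_nontarget[i], n$n_target[i],
                n$percent[i]))
  }
  invisible(x)
}

#' @export
as.data.frame.tree_report <- function(x, ...) x$nodes
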