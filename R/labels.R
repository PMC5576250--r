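#' Assign positive-unlabelled labels from a development-stage table
#'
#' A gene is labelled a target (1) if it has at least one programme in a
#' positive development stage; its best stage is the most advanced one under
#' the precedence order Preclinical < Clinical Trial < Phase I < Phase II <
#' Phase III < Pre-registration < Registered < Launched. Genes with only
#' failed-programme stages (suspended, discontinued, withdrawn) or absent
#' from the table stay unlabelled (0): the unlabelled set is treated as the
#' negative class downstream. Unknown stage strings are rejected with a
#' warning.
#'
#' @param stage_records Data frame with columns `gene` and `stage`.
#' @param gene_universe Character vector of all gene ids to label.
#' @param positive Positive-stage vocabulary in precedence order.
#' @param failed Failed-programme vocabulary.
#' @return Data frame with columns `gene_id`, `label` (0/1), `best_stage`
#'   (NA for unlabelled genes).
#' @export
assign_labels <- function(stage_records, gene_universe,
                          positive = POSITIVE_STAGES,
                          failed = FAILED_STAGES) {
  stopifnot(is.data.frame(stage_records),
            all(c("gene", "stage") %in% names(stage_records)))
  known <- stage_records$stage %in% c(positive, failed)
  if (any(!known))
    warnf("rejected %d stage record(s) with unknown stage(s): %s",
          sum(!known),
          paste(unique(stage_records$stage[!known]), collapse = ", "))
  sr <- stage_records[known & stage_records$stage %in% positive, , drop = FALSE]
  rank <- match(sr$stage, positive)
  best <- tapply(rank, factor(sr$gene, levels = unique(sr$gene)), max)
  out <- data.frame(gene_id = gene_universe,
                    label = 0L, best_stage = NA_character_,
                    stringsAsFactors = FALSE)
  hit <- match(out$gene_id, names(best))
  has <- !is.na(hit)
  out$label[has] <- 1L
  out$best_stage[has] <- positive[best[hit[has]]]
  out
}

#' Construct the balanced working set and train/test/prediction partition
#'
#' All positives are taken into the working set together with an equal number
#' of unlabelled genes sampled without replacement; the remaining unlabelled
#' genes form the prediction set. The working set is then split into training
#' and test portions (default 80/20), stratified by label so both classes are
#' equally represented in each portion.
#'
#' @param labels Data frame from [assign_labels()] (`gene_id`, `label`).
#' @param train_fraction Fraction of the working set used for training.
#' @param seed Integer seed for the unlabelled sampling and the split.
#' @return Data frame with columns `gene_id`, `label`, `partition`
#'   (`"train"`, `"test"` or `"prediction"`), of class `pu_partition`.
#' @export
make_working_split <- function(labels, train_fraction = 0.8, seed = 1L) {
  stopifnot(is.data.frame(labels), all(c("gene_id", "label") %in% names(labels)))
  if (!(train_fraction > 0 && train_fraction < 1))
    stopf("train_fraction must be in (0,1)")
  pos <- labels$gene_id[labels$label == 1L]
  unl <- labels$gene_id[labels$label == 0L]
  n_pos <- length(pos)
  if (n_pos < 2) stopf("need at least 2 positive genes, got %d", n_pos)
  if (length(unl) < n_pos)
    stopf("unlabelled genes (%d) fewer than positives (%d)",
          length(unl), n_pos)
  withr::with_seed(as.integer(seed), {
    sampled_unl <- sample(unl, n_pos)
    n_train <- round(train_fraction * n_pos)
    train_pos <- sample(pos, n_train)
    train_unl <- sample(sampled_unl, n_train)
  })
  out <- data.frame(gene_id = labels$gene_id, label = labels$label,
                    partition = "prediction", stringsAsFactors = FALSE)
  working <- c(pos, sampled_unl)
  out$partition[out$gene_id %in% working] <- "test"
  out$partition[out$gene_id %in% c(train_pos, train_unl)] <- "train"
  class(out) <- c("pu_partition", class(out))
  out
}

#' @export
print.pu_partition <- function(x, ...) {
  tab <- table(partition = x$partition, label = x$label)
  cat("PU partition:", nrow(x), "genes\n")
  print(tab)
  invisible(x)
}
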