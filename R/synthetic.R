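#' Configuration for the synthetic evidence generator
#'
#' Describes a zero-inflated Beta generative model for gene-disease evidence
#' scores. Each gene is either a true (potential) target or background; for
#' every (gene, disease, data type) triple a record is emitted with a
#' class-dependent activation probability, and active records draw their
#' score from a class-dependent Beta distribution. Only a fraction of true
#' targets is observed as labelled positives, selected completely at random
#' (SCAR), so the unlabelled class is contaminated with hidden positives --
#' the regime a positive-unlabelled learner has to cope with.
#'
#' @param n_genes Number of genes (>= 2).
#' @param n_diseases Number of diseases; evidence is i.i.d. across diseases.
#' @param true_target_fraction Fraction of genes that are true targets, in (0,1).
#' @param labelled_fraction Fraction of true targets observed as positives, in (0,1].
#' @param signal_features Data types whose activation and score distributions
#'   differ between classes.
#' @param activation_prob_target,activation_prob_background Per-data-type
#'   probability that a (gene, disease) pair emits a record, for target and
#'   background genes. Either a single number or a named vector over the
#'   seven data types. Defaults concentrate the class signal in the animal
#'   model, RNA-expression and genetic-association channels and make
#'   known_drug strongly label-dependent (it is a leakage feature and is
#'   excluded downstream).
#' @param score_shape_target,score_shape_background Beta shape pairs for
#'   active scores of signal features in targets vs everything else.
#' @param indirect_fraction Fraction of records flagged as indirect
#'   (ontology-propagated) associations.
#' @param seed Integer seed; the record stream is a deterministic function of it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000,
                             n_diseases = 50,
                             true_target_fraction = 0.1,
                             labelled_fraction = 0.5,
                             signal_features = c("animal_model",
                                                 "rna_expression",
                                                 "genetic_association"),
                             activation_prob_target = NULL,
                             activation_prob_background = 0.03,
                             score_shape_target = c(3, 2),
                             score_shape_background = c(1.2, 4),
                             indirect_fraction = 0.2,
                             seed = 1L) {
  if (n_genes < 2) stopf("n_genes must be >= 2")
  if (n_diseases < 1) stopf("n_diseases must be >= 1")
  if (!(true_target_fraction > 0 && true_target_fraction < 1))
    stopf("true_target_fraction must be in (0,1)")
  if (!(labelled_fraction > 0 && labelled_fraction <= 1))
    stopf("labelled_fraction must be in (0,1]")
  if (!all(signal_features %in% OT_DATA_TYPES))
    stopf("unknown signal feature(s): %s",
          paste(setdiff(signal_features, OT_DATA_TYPES), collapse = ", "))

  expand_prob <- function(p, default) {
    out <- rep(default, length(OT_DATA_TYPES))
    names(out) <- OT_DATA_TYPES
    if (is.null(p)) return(out)
    if (is.null(names(p))) {
      out[] <- p
    } else {
      bad <- setdiff(names(p), OT_DATA_TYPES)
      if (length(bad)) stopf("unknown data type(s) in activation prob: %s",
                             paste(bad, collapse = ", "))
      out[names(p)] <- p
    }
    out
  }

  bg <- expand_prob(activation_prob_background, 0.03)
  if (is.null(activation_prob_target)) {
    tg <- bg
    tg[signal_features] <- 0.12
    tg["known_drug"] <- 0.25     # leakage channel, dropped by the default FeatureConfig
  } else {
    tg <- expand_prob(activation_prob_target, 0.03)
  }
  if (!is_prob(tg) || !is_prob(bg))
    stopf("activation probabilities must lie in [0,1]")
  if (any(tg[signal_features] < bg[signal_features]))
    stopf("activation_prob_target must be >= activation_prob_background for signal features")
  check_shape <- function(s, what) {
    if (length(s) != 2 || !all(is.finite(s)) || any(s <= 0))
      stopf("%s must be a pair of positive reals", what)
  }
  check_shape(score_shape_target, "score_shape_target")
  check_shape(score_shape_background, "score_shape_background")
  if (!(indirect_fraction >= 0 && indirect_fraction <= 1))
    stopf("indirect_fraction must be in [0,1]")

  structure(list(
    n_genes = as.integer(n_genes),
    n_diseases = as.integer(n_diseases),
    true_target_fraction = true_target_fraction,
    labelled_fraction = labelled_fraction,
    signal_features = signal_features,
    activation_prob_target = tg,
    activation_prob_background = bg,
    score_shape_target = score_shape_target,
    score_shape_background = score_shape_background,
    indirect_fraction = indirect_fraction,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate synthetic gene-disease evidence records with ground truth
#'
#' Emits one evidence record per activated (gene, disease, data type) triple,
#' with scores drawn from the class-specific Beta distribution, and returns
#' the ground-truth class and observation status of every gene alongside.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `records` (data frame: `gene`, `disease`,
#'   `datatype`, `score`, `is_direct`) and `truth` (data frame: `gene_id`,
#'   `true_target`, `observed_positive`).
#' @export
generate_evidence <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    genes <- sprintf("G%05d", seq_len(config$n_genes))
    diseases <- sprintf("D%04d", seq_len(config$n_diseases))

    n_true <- max(1L, round(config$n_genes * config$true_target_fraction))
    true_idx <- sort(sample.int(config$n_genes, n_true))
    n_obs <- max(1L, round(n_true * config$labelled_fraction))
    obs_idx <- sort(sample(true_idx, n_obs))
    is_true <- seq_len(config$n_genes) %in% true_idx

    parts <- vector("list", length(OT_DATA_TYPES))
    for (k in seq_along(OT_DATA_TYPES)) {
      dt <- OT_DATA_TYPES[k]
      p_gene <- ifelse(is_true,
                       config$activation_prob_target[dt],
                       config$activation_prob_background[dt])
      ## genes vary fastest; disease blocks are contiguous
      p_all <- rep(p_gene, times = config$n_diseases)
      active <- which(stats::runif(length(p_all)) < p_all)
      if (!length(active)) next
      g_idx <- (active - 1L) %% config$n_genes + 1L
      d_idx <- (active - 1L) %/% config$n_genes + 1L
      signal_rec <- is_true[g_idx] & dt %in% config$signal_features
      score <- numeric(length(active))
      if (any(signal_rec))
        score[signal_rec] <- stats::rbeta(sum(signal_rec),
                                          config$score_shape_target[1],
                                          config$score_shape_target[2])
      if (any(!signal_rec))
        score[!signal_rec] <- stats::rbeta(sum(!signal_rec),
                                           config$score_shape_background[1],
                                           config$score_shape_background[2])
      parts[[k]] <- data.frame(
        gene = genes[g_idx], disease = diseases[d_idx],
        datatype = dt, score = score, stringsAsFactors = FALSE
      )
    }
    records <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
    if (is.null(records)) {
      records <- data.frame(gene = character(), disease = character(),
                            datatype = character(), score = numeric(),
                            is_direct = logical(), stringsAsFactors = FALSE)
    } else {
      records$is_direct <- stats::runif(nrow(records)) >= config$indirect_fraction
      rownames(records) <- NULL
    }

    truth <- data.frame(
      gene_id = genes,
      true_target = is_true,
      observed_positive = seq_len(config$n_genes) %in% obs_idx,
      stringsAsFactors = FALSE
    )
    list(records = records, truth = truth)
  })
}

#' Generate a development-stage table from ground truth
#'
#' Every observed positive receives one stage drawn uniformly from the
#' positive-stage vocabulary, plus (with probability `multi_stage_prob`) a
#' second distinct stage, emulating programmes running at several phases.
#' A fraction of the non-positive genes receives a failed-programme stage
#' (suspended / discontinued / withdrawn) to exercise the exclusion logic;
#' failed stages are never generated for observed positives.
#'
#' @param truth Ground-truth data frame from [generate_evidence()].
#' @param multi_stage_prob Probability that an observed positive has a second
#'   stage row.
#' @param failed_stage_fraction Fraction of non-positive genes given a failed
#'   stage row.
#' @param seed Integer seed.
#' @return Data frame with columns `gene` and `stage` (one row per programme).
#' @export
generate_stage_table <- function(truth, multi_stage_prob = 0.3,
                                 failed_stage_fraction = 0.05, seed = 1L) {
  stopifnot(is.data.frame(truth), all(c("gene_id", "observed_positive") %in% names(truth)))
  withr::with_seed(as.integer(seed), {
    pos <- truth$gene_id[truth$observed_positive]
    rows <- list()
    if (length(pos)) {
      first <- sample(POSITIVE_STAGES, length(pos), replace = TRUE)
      rows[[1]] <- data.frame(gene = pos, stage = first, stringsAsFactors = FALSE)
      extra <- stats::runif(length(pos)) < multi_stage_prob
      if (any(extra)) {
        second <- vapply(first[extra], function(s)
          sample(setdiff(POSITIVE_STAGES, s), 1L), character(1))
        rows[[2]] <- data.frame(gene = pos[extra], stage = unname(second),
                                stringsAsFactors = FALSE)
      }
    }
    neg <- truth$gene_id[!truth$observed_positive]
    if (length(neg) && failed_stage_fraction > 0) {
      pick <- stats::runif(length(neg)) < failed_stage_fraction
      if (any(pick))
        rows[[length(rows) + 1L]] <- data.frame(
          gene = neg[pick],
          stage = sample(FAILED_STAGES, sum(pick), replace = TRUE),
          stringsAsFactors = FALSE)
    }
    if (!length(rows))
      return(data.frame(gene = character(), stage = character(),
                        stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic literature gene list
#'
#' Emulates the output of text mining the literature for proposed therapeutic
#' targets: genes are sampled without replacement with weight
#' `enrichment_factor` for true targets and 1 otherwise, so the list is
#' enriched for true targets when `enrichment_factor > 1` and uniform random
#' when it equals 1.
#'
#' @param truth Ground-truth data frame from [generate_evidence()].
#' @param enrichment_factor Sampling weight multiplier for true targets (>= 1).
#' @param size Number of genes in the list (<= number of genes).
#' @param seed Integer seed.
#' @return Character vector of gene ids.
#' @export
generate_literature_list <- function(truth, enrichment_factor = 1, size, seed = 1L) {
  stopifnot(is.data.frame(truth))
  if (enrichment_factor < 1) stopf("enrichment_factor must be >= 1")
  size <- as.integer(size)
  if (size > nrow(truth)) stopf("size (%d) exceeds number of genes (%d)",
                                size, nrow(truth))
  if (size == 0L) return(character())
  withr::with_seed(as.integer(seed), {
    w <- ifelse(truth$true_target, enrichment_factor, 1)
    sample(truth$gene_id, size, prob = w)
  })
}

#' Write evidence records to disk
#'
#' @param records Evidence data frame (`gene`, `disease`, `datatype`, `score`,
#'   `is_direct`).
#' @param path Output file path.
#' @param format `"jsonl"` (one JSON object per line) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_evidence <- function(records, path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    lines <- sprintf(
      '{"gene":"%s","disease":"%s","datatype":"%s","score":%s,"is_direct":%s}',
      records$gene, records$disease, records$datatype,
      formatC(records$score, format = "g", digits = 17),
      ifelse(records$is_direct, "true", "false"))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Write a stage table, literature list or ground-truth table
#'
#' Plain TSV writers for the remaining pipeline inputs.
#' @param x Data frame (stage table / ground truth) or character vector
#'   (literature list).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stage_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stage_table
#' @export
write_gene_list <- function(x, path) {
  writeLines(c("gene", as.character(x)), path)
  invisible(path)
}

#' Read a one-column gene list written by [write_gene_list()]
#' @param path File path.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  as.character(x[[1]])
}
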