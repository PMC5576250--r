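#' Pipeline configuration
#'
#' Collects every stage's settings for an end-to-end run: input locations
#' (or a synthetic-data specification), feature construction, the balanced
#' working split, the production classifier and its bagging, optional
#' benchmarking and stability analysis, the prediction probability
#' threshold, and the enrichment validation. A single global seed fans out
#' to per-stage seeds through a fixed derivation, so each stage is
#' independently reproducible.
#'
#' @param evidence_path,stage_path,literature_path Input files (evidence
#'   records, development stages, external gene list). Ignored when
#'   `synthetic` is given.
#' @param evidence_format `"jsonl"` or `"tsv"`.
#' @param synthetic Optional [synthetic_config()]; when supplied the three
#'   inputs are generated (and written to the output directory) instead of
#'   read.
#' @param feature A [feature_config()].
#' @param train_fraction Training fraction of the working set.
#' @param learner Production classifier specification (default the bagged
#'   single-hidden-layer neural network).
#' @param n_bags,aggregate Bagging settings for the production fit.
#' @param benchmark_specs Optional named list of [base_learner()]s to
#'   benchmark with nested CV before the production fit.
#' @param cv A [cv_config()] used when benchmarking.
#' @param n_permutations Permutations for the enrichment null (0 disables).
#' @param universe_size Gene universe for the enrichment test; `NULL` uses
#'   the number of genes in the feature matrix.
#' @param probability_threshold Probability cut-off above which an unlabelled
#'   gene is nominated as a novel target (default 0.9).
#' @param out_dir Output directory for all artefacts.
#' @param seed Global integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(evidence_path = NULL,
                            evidence_format = c("jsonl", "tsv"),
                            stage_path = NULL,
                            literature_path = NULL,
                            synthetic = NULL,
                            feature = feature_config(),
                            train_fraction = 0.8,
                            learner = base_learner("feedforward_nn_1hidden"),
                            n_bags = 100,
                            aggregate = "mean_prob",
                            benchmark_specs = NULL,
                            cv = cv_config(),
                            n_permutations = 1000,
                            universe_size = NULL,
                            probability_threshold = 0.9,
                            out_dir = "putarget-output",
                            seed = 1L) {
  evidence_format <- match.arg(evidence_format)
  if (is.null(synthetic) &&
      (is.null(evidence_path) || is.null(stage_path)))
    stopf("either a synthetic config or evidence_path + stage_path is required")
  if (!(probability_threshold > 0 && probability_threshold < 1))
    stopf("probability_threshold must be in (0,1)")
  structure(list(
    evidence_path = evidence_path, evidence_format = evidence_format,
    stage_path = stage_path, literature_path = literature_path,
    synthetic = synthetic, feature = feature,
    train_fraction = train_fraction, learner = learner,
    n_bags = n_bags, aggregate = aggregate,
    benchmark_specs = benchmark_specs, cv = cv,
    n_permutations = n_permutations, universe_size = universe_size,
    probability_threshold = probability_threshold,
    out_dir = out_dir, seed = as.integer(seed)
  ), class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full target-prediction pipeline
#'
#' Executes every stage end-to-end: input acquisition (synthetic generation
#' or file reading), feature-matrix construction, stage-based labelling and
#' the balanced working split, optional nested-CV benchmarking, fitting the
#' production bagged classifier, held-out test evaluation, ranked prediction
#' of novel targets above the probability threshold, feature importance and
#' inspection tree, and literature-overlap enrichment with a permutation
#' null. All artefacts are written to the configured output directory as
#' TSV/JSON; a manifest records the configuration hash and derived seeds.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the key objects (feature matrix,
#'   partition, fitted model, test metrics, prediction table, enrichment
#'   result, paths to all artefacts).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(config$out_dir, f)
  seeds <- list(synthetic = derive_seed(config$seed, 1),
                split = derive_seed(config$seed, 2),
                fit = derive_seed(config$seed, 3),
                cv = derive_seed(config$seed, 4),
                permutation = derive_seed(config$seed, 5))
  artefacts <- character()

  ## -- inputs ------------------------------------------------------------
  truth <- NULL
  inputs <- run_stage("inputs", {
    if (!is.null(config$synthetic)) {
      sc <- config$synthetic
      sc$seed <- seeds$synthetic
      gen <- generate_evidence(sc)
      truth <- gen$truth
      stages <- generate_stage_table(gen$truth, seed = seeds$synthetic)
      literature <- generate_literature_list(
        gen$truth, enrichment_factor = 5,
        size = max(1L, round(nrow(gen$truth) / 5)), seed = seeds$synthetic)
      write_evidence(gen$records, pth("evidence.jsonl"))
      write_stage_table(stages, pth("stages.tsv"))
      write_gene_list(literature, pth("literature.tsv"))
      write_stage_table(gen$truth, pth("ground_truth.tsv"))
      list(records = gen$records, stages = stages, literature = literature,
           universe = gen$truth$gene_id)
    } else {
      records <- read_evidence(config$evidence_path, config$evidence_format)
      stages <- utils::read.delim(config$stage_path, stringsAsFactors = FALSE)
      literature <- if (is.null(config$literature_path)) character() else
        read_gene_list(config$literature_path)
      list(records = records, stages = stages, literature = literature,
           universe = NULL)
    }
  })

  ## -- features ----------------------------------------------------------
  features <- run_stage("features", {
    m <- build_feature_matrix(inputs$records, config$feature,
                              universe = inputs$universe)
    write_feature_matrix(m, pth("feature_matrix.tsv"))
    m
  })

  ## -- labelling and split ----------------------------------------------
  split <- run_stage("labelling", {
    labels <- assign_labels(inputs$stages, rownames(features))
    part <- make_working_split(labels, config$train_fraction,
                               seed = seeds$split)
    part$best_stage <- labels$best_stage[match(part$gene_id, labels$gene_id)]
    write_stage_table(part, pth("partitions.tsv"))
    part
  })
  xg <- function(p) features[split$gene_id[split$partition %in% p], ,
                             drop = FALSE]
  yg <- function(p) split$label[split$partition %in% p]

  ## -- optional benchmark -------------------------------------------------
  bench <- NULL
  if (!is.null(config$benchmark_specs)) {
    bench <- run_stage("benchmark", {
      cvc <- config$cv
      cvc$seed <- seeds$cv
      b <- benchmark_classifiers(config$benchmark_specs,
                                 xg("train"), yg("train"), config = cvc,
                                 n_bags = config$n_bags,
                                 aggregate = config$aggregate)
      utils::write.table(b$table, pth("benchmark.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      b
    })
  }

  ## -- production fit and test evaluation --------------------------------
  model <- run_stage("fit", {
    m <- pu_bag(xg("train"), yg("train"), config$learner,
                n_bags = config$n_bags, aggregate = config$aggregate,
                seed = seeds$fit)
    save_pu_bag(m, pth("model.rds"))
    m
  })
  test_metrics <- run_stage("test_evaluation", {
    rep <- evaluate_on_test(model, xg("test"), yg("test"),
                            train_ids = split$gene_id[split$partition == "train"])
    out <- rep[c("misclassification_error", "accuracy", "auc",
                 "sensitivity_recall", "specificity", "precision", "f1")]
    out$confusion <- as.list(stats::setNames(as.integer(rep$confusion),
                                             names(rep$confusion)))
    jsonlite::write_json(out, pth("test_metrics.json"), auto_unbox = TRUE,
                         digits = NA)
    rep
  })

  ## -- ranked predictions -------------------------------------------------
  predictions <- run_stage("prediction", {
    xp <- xg("prediction")
    tab <- predict(model, xp, type = "table",
                   threshold = config$probability_threshold)
    tab <- data.frame(gene = rownames(xp), tab, stringsAsFactors = FALSE)
    tab <- tab[order(-tab$prob_target), ]
    rownames(tab) <- NULL
    utils::write.table(tab, pth("predictions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tab
  })

  ## -- interpretation ------------------------------------------------------
  interpretation <- run_stage("interpretation", {
    imp <- feature_importance(xg(c("train", "test")), yg(c("train", "test")))
    utils::write.table(imp, pth("feature_importance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tree <- fit_inspection_tree(xg("train"), yg("train"))
    utils::write.table(tree$nodes, pth("inspection_tree.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(importance = imp, tree = tree)
  })

  ## -- enrichment validation ----------------------------------------------
  enrichment <- NULL
  if (length(inputs$literature)) {
    enrichment <- run_stage("enrichment", {
      predicted <- predictions$gene[predictions$class == 1L]
      working <- split$gene_id[split$partition != "prediction"]
      usize <- if (is.null(config$universe_size)) nrow(features) else
        config$universe_size
      enr <- overlap_enrichment(predicted, inputs$literature,
                                exclusions = working, universe_size = usize)
      out <- list(overlap = enr$overlap, odds_ratio = enr$odds_ratio,
                  p_value = enr$p_value, universe_size = usize,
                  n_predicted = length(setdiff(predicted, working)),
                  n_reference = length(setdiff(unique(inputs$literature),
                                               working)))
      if (config$n_permutations > 0) {
        null <- permutation_null(out$n_predicted, out$n_reference, usize,
                                 n_permutations = config$n_permutations,
                                 seed = seeds$permutation, compute_p = FALSE)
        out$null_mean_odds_ratio <- unname(null$summary["mean_odds_ratio"])
        out$null_sd_odds_ratio <- unname(null$summary["sd_odds_ratio"])
      }
      jsonlite::write_json(out, pth("enrichment.json"), auto_unbox = TRUE,
                           digits = NA)
      out
    })
  }

  ## -- manifest ------------------------------------------------------------
  run_stage("manifest", {
    cfg_file <- pth("config.yaml")
    yaml::write_yaml(serialise_config(config), cfg_file)
    manifest <- list(
      package_version = as.character(utils::packageVersion("putarget")),
      config_md5 = unname(tools::md5sum(cfg_file)),
      global_seed = config$seed,
      stage_seeds = seeds,
      n_genes = nrow(features),
      n_positives = sum(split$label)
    )
    jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE)
  })

  invisible(list(features = features, partition = split, model = model,
                 benchmark = bench, test_metrics = test_metrics,
                 predictions = predictions, interpretation = interpretation,
                 enrichment = enrichment, out_dir = config$out_dir))
}

## Flatten a pipeline_config into plain lists for the YAML manifest; the
## manifest is for provenance, not for re-parsing. The output directory is
## not part of the settings, so two runs of the same analysis in different
## places hash identically.
serialise_config <- function(config) {
  config$out_dir <- NULL
  drop_class <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, drop_class)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  drop_class(unclass(config))
}
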