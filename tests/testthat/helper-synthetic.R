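## Shared fixture builders. All data is generated in code at test time.

## Graded class signal (animal model strongest, then RNA expression, then
## genetic association), mirroring the ordering the importance and tree
## analyses are expected to recover.
strong_config <- function(n_genes = 600, n_diseases = 20, seed = 1,
                          true_target_fraction = 0.2,
                          labelled_fraction = 0.5) {
  synthetic_config(
    n_genes = n_genes, n_diseases = n_diseases,
    true_target_fraction = true_target_fraction,
    labelled_fraction = labelled_fraction,
    activation_prob_target = c(animal_model = 0.45, rna_expression = 0.15,
                               genetic_association = 0.10),
    activation_prob_background = 0.03,
    score_shape_target = c(4, 2),
    score_shape_background = c(1.2, 4),
    seed = seed)
}

## No class signal at all: activation and score shapes identical across
## classes; any downstream classifier should be at chance against truth.
null_config <- function(n_genes = 300, n_diseases = 15, seed = 1) {
  synthetic_config(
    n_genes = n_genes, n_diseases = n_diseases,
    true_target_fraction = 0.1, labelled_fraction = 0.5,
    signal_features = character(0),
    activation_prob_target = 0.05, activation_prob_background = 0.05,
    score_shape_target = c(1.5, 3), score_shape_background = c(1.5, 3),
    seed = seed)
}

## Generator -> feature matrix -> labels -> balanced split, in one step.
make_pu_data <- function(config, split_seed = config$seed) {
  gen <- generate_evidence(config)
  m <- build_feature_matrix(gen$records, feature_config(),
                            universe = gen$truth$gene_id)
  stages <- generate_stage_table(gen$truth, seed = config$seed)
  labels <- assign_labels(stages, rownames(m))
  part <- make_working_split(labels, seed = split_seed)
  list(features = m, truth = gen$truth, labels = labels, partition = part,
       records = gen$records, stages = stages)
}

part_x <- function(d, parts) {
  d$features[d$partition$gene_id[d$partition$partition %in% parts], ,
             drop = FALSE]
}
part_y <- function(d, parts) {
  d$partition$label[d$partition$partition %in% parts]
}
truth_of <- function(d, ids) {
  as.integer(d$truth$true_target[match(ids, d$truth$gene_id)])
}

## Two well-separated Gaussian clouds in 5 dimensions.
make_clouds <- function(n = 100, seed = 1, sep = 3) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    x <- matrix(stats::rnorm(n * 5), ncol = 5,
                dimnames = list(sprintf("R%03d", seq_len(n)),
                                paste0("f", 1:5)))
    x[y == 1, ] <- x[y == 1, ] + sep
    list(x = x, y = y)
  })
}

## XOR-pattern data: unlearnable by a depth-1 tree, easy at depth >= 2.
make_xor <- function(n = 200, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(stats::runif(n * 2), ncol = 2,
                dimnames = list(NULL, c("u", "v")))
    y <- as.integer(xor(x[, 1] > 0.5, x[, 2] > 0.5))
    list(x = x, y = y)
  })
}
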