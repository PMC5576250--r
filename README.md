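# putarget

Semi-supervised prediction of therapeutic drug targets from gene–disease
association evidence.

## The problem

Most genes have never been pursued as drug targets, but that does not make
them non-targets: some are future targets that nobody has gotten to yet.
Labels for this problem are therefore *positive and unlabelled* (PU): a set
of known targets — genes with a drug on the market or in active development —
and a large unlabelled remainder that silently mixes true negatives with
hidden positives. `putarget` implements a complete PU-learning pipeline that
asks whether a gene's profile of disease-association evidence (pathway
membership, animal-model phenotypes, germline genetics, differential RNA
expression, somatic mutations — each scored in [0, 1] per disease) is enough
to recognise the genes the pharmaceutical industry works on, and to nominate
new ones.

The pipeline:

1. **Evidence aggregation** — per-gene, per-data-type pan-disease mean
   scores form a genes × 5 feature matrix `X`. Indirect
   (ontology-propagated) associations are removed, low-confidence
   animal-model records (score < 0.4) are dropped before averaging, and the
   `known_drug` / `literature` channels are excluded (the former is the
   outcome in disguise, the latter is reserved for validation).
2. **PU labelling** — a gene is a positive (`y = 1`) if it has a programme
   in any active development stage (Preclinical through Launched; the most
   advanced stage is kept); suspended/discontinued/withdrawn programmes do
   not count. Everything else is unlabelled and treated as `y = 0`.
3. **Balanced working set** — all `P` positives plus `P` randomly sampled
   unlabelled genes, split 80/20 into train/test; the remaining unlabelled
   genes form the prediction set.
4. **Bagged classification** — an ensemble of `B = 100` base classifiers
   (random forest, radial SVM, single-hidden-layer neural network,
   exponential-loss boosting, or CART), each fitted on a bootstrap resample
   of the training rows; the ensemble score is the mean positive-class
   probability (or the vote fraction). Bagging damps the instability that
   hidden positives induce.
5. **Nested cross-validation** — a fourfold inner loop tunes
   hyperparameters, a fourfold outer loop estimates performance without
   leaking tuning information; a Monte-Carlo loop over re-drawn unlabelled
   sets quantifies sampling stability.
6. **Prediction and validation** — unlabelled genes with ensemble
   probability above 0.9 are nominated as novel targets, and the nominated
   set is checked against an external literature gene list with a two-sided
   Fisher's exact test plus a permutation null (independent random sets of
   the same sizes; the sample odds ratio `(ad)/(bc)` is ≈ 1 under the null).

Because the licensed data sources this kind of analysis runs on cannot be
redistributed, the package ships a synthetic-data generator
(`synthetic_config()`, `generate_evidence()`) producing sparse zero-inflated
Beta evidence with class signal in the animal-model / RNA-expression /
genetic-association channels and a SCAR-contaminated unlabelled class, with
ground truth attached for property testing.

## Worked example

```r
library(putarget)

cfg <- synthetic_config(n_genes = 2000, seed = 42)
sim <- generate_evidence(cfg)
features <- build_feature_matrix(sim$records, feature_config(),
                                 universe = sim$truth$gene_id)
stages <- generate_stage_table(sim$truth, seed = 42)
labels <- assign_labels(stages, rownames(features))
part <- make_working_split(labels, seed = 42)
print(part)
#> PU partition: 2000 genes
#>             label
#> partition       0    1
#>   prediction 1800    0
#>   test         20   20
#>   train        80   80

train <- part$partition == "train"
fit <- pu_bag(features[part$gene_id[train], ], part$label[train],
              base_learner("feedforward_nn_1hidden", size = 3),
              n_bags = 25, seed = 42)

test <- part$partition == "test"
report <- evaluate_on_test(fit, features[part$gene_id[test], ],
                           part$label[test], train_ids = part$gene_id[train])
print(report)
#> misclassification_error  0.025
#> accuracy                 0.975
#> auc                      1.000
#> sensitivity_recall       0.950
#> specificity              1.000
#> precision                1.000
#> f1                       0.974

pred_ids <- part$gene_id[part$partition == "prediction"]
pred <- predict(fit, features[pred_ids, ], type = "table", threshold = 0.9)
sum(pred$class)
#> [1] 71
```

100 of the 2000 synthetic genes are observed positives, so the balanced
working set has 200 genes (160 train / 40 test) and 1800 genes remain for
prediction. The held-out metrics read as usual (accuracy, AUC by midrank
Mann–Whitney, sensitivity, specificity, precision, F1) — but note that with
hidden positives in the "negative" class the apparent false-positive rate
*over*states the true one, and sensitivity/precision understate it. The 71
genes with ensemble probability > 0.9 are the nominated novel targets; on
this synthetic run they are strongly enriched for planted true targets.

`run_pipeline(pipeline_config(...))` chains all of the above (plus optional
benchmarking of all five families, feature importance by chi-squared /
information gain, an inspection decision tree and the enrichment validation)
and writes every artefact — feature matrix, partitions, benchmark table,
test metrics, ranked predictions, enrichment report, manifest — to an output
directory. `inst/cli/putarget.R` exposes the same steps as shell
subcommands.

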