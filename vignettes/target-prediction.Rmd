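---
title: "Predicting therapeutic targets from positive–unlabelled gene–disease evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting therapeutic targets from positive–unlabelled gene–disease evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(putarget)
```

## The statistical setting

`putarget` treats drug-target discovery as binary classification under
positive–unlabelled (PU) labels. The observations are genes; the features
are five pan-disease evidence scores in $[0,1]$ (affected pathway, animal
model, genetic association, RNA expression, somatic mutation); the label is
1 for genes with an active drug-development programme and 0 for everything
else. The crucial asymmetry is that the 0 class is *unlabelled*, not
negative: it contains both genes that will never be targets and genes that
simply have not been pursued yet. We nonetheless train ordinary supervised
classifiers with the unlabelled set as the negative class — the standard PU
device — and rely on two mitigations:

* **A balanced working set.** All $P$ positives plus $P$ unlabelled genes
  sampled without replacement; the rest of the unlabelled genes become the
  prediction set. Balance stops the classifier from collapsing onto the
  majority class, and the untouched prediction set is where novel targets
  are nominated.
* **Bootstrap aggregation.** Hidden positives make any single fit unstable:
  which contaminating genes land in the training sample changes the
  decision boundary. Fitting `n_bags = 100` base models on with-replacement
  resamples of the training rows and averaging their probabilities reduces
  this variance. Random forests already bag internally, so for that family
  the ensemble is a single forest on the full training set.

Two consequences of PU labelling are worth keeping in mind when reading any
of the performance numbers. Measured against PU labels, the false-positive
rate is *over*estimated (hidden positives that the model correctly flags
count as false positives) and sensitivity and precision are
*under*estimated. The package's test suite verifies the first property
directly on synthetic data where ground truth is known.

## Feature construction

Raw evidence records are `(gene, disease, data type, score, direct?)`
tuples. The design matrix is built by:

1. dropping indirect associations (evidence propagated to ancestor disease
   terms in the ontology; keeping them would double-count),
2. dropping the `known_drug` data type (it is essentially the label) and
   `literature` (reserved as the external validation source),
3. dropping animal-model records with score below
   `animal_model_min_score = 0.4`, *before* averaging — the wording of the
   underlying data-processing convention reads as a record-level filter,
   and this is the package default; a post-aggregation variant
   (`animal_model_filter = "aggregate"`) is available for sensitivity
   analysis,
4. averaging the remaining scores per gene and data type across the
   diseases that retain at least one record ("pan-disease mean"), and
5. encoding absent (gene, data type) evidence as 0. The real matrices this
   emulates are extremely sparse with most values near zero, so zero is the
   natural fill; no convention for the fill value is stated anywhere, and
   this choice is deliberate and documented rather than forced.

By default a gene appears in the matrix only if it retains at least one
record; passing a `universe` adds all-zero rows, which is needed when the
downstream labelling should cover genes whose entire evidence was filtered
away.

## Labelling and splitting

A gene is positive if it has at least one programme in
Preclinical < Clinical Trial < Phase I < Phase II < Phase III <
Pre-registration < Registered < Launched (that order also defines the
"best" stage kept for the stage-association analysis). Suspended,
discontinued and withdrawn programmes are ignored when building the
positive set — a failed programme is weak evidence either way, since drugs
are withdrawn for commercial as well as biological reasons.

The 80/20 train/test split is stratified by label. Stratification is a
design choice: with a balanced working set, near-balanced test classes are
what makes the test confusion matrix interpretable, and fold construction
in the cross-validation loops is stratified for the same reason. The
unlabelled half of the working set is sampled *without* replacement so that
no gene can appear in both the working and prediction sets.

One arithmetic convention matters for reproducing published set sizes: the
per-class training count is `round(0.8 * P)`. With 1,421 positives this
gives 1,137 + 1,137 = 2,274 training and 284 + 284 = 568 test observations,
and 18,104 − 2,842 = 15,262 prediction genes — exactly the margins the
package's acceptance tests assert.

## Model selection and evaluation

Hyperparameters are tuned by nested cross-validation: a fourfold inner loop
grid-searches on each outer-training portion (minimising misclassification
error, the classical default tuning measure), and a fourfold outer loop
evaluates a refitted model once per fold on rows never seen during tuning.
The implementation stores the inner-fold assignments so the test suite can
assert, fold by fold, that outer-test ids never intersect inner-training
ids. With a single-point grid the inner loop is skipped and the procedure
reduces to plain stratified k-fold evaluation — a degeneracy the tests also
verify against an independent k-fold run.

The default tuning grids are: random forest, trees {250, 500, 1000} ×
features-per-split {1, 2, 3}; neural network, hidden size {1, 3, 5, 8} ×
weight decay {0, 0.01, 0.1}; SVM, gamma {0.1, 0.5, 1, 2} × cost
{0.5, 1, 2, 4}; boosting, trees {100, 300, 1000} × depth {1, 2, 3}. No
grids are prescribed by the method itself; these are conventional ranges
and fully configurable.

Metrics are computed from the confusion matrix (accuracy, sensitivity,
specificity, precision, F1, misclassification error = 1 − accuracy to
machine precision); undefined ratios (zero denominators) are reported as
`NA`, never as 0. AUC is the midrank Mann–Whitney statistic normalised by
$n_1 n_0$, which equals trapezoidal integration of the ROC curve and is
invariant under monotone score transforms. Classification at a threshold is
strict (`score > t`), so exact ties resolve to non-target — the
conservative direction when nominating targets. Novel targets are
nominated at `probability_threshold = 0.9` rather than 0.5 to trade recall
for precision in the nomination list.

The probability being thresholded is, by default, the **mean of per-bag
probabilities**. Majority voting is the classical aggregation for class
decisions, but a continuous score is required both for the 0.9 cut-off and
for ROC analysis; the vote fraction is available as an alternative
aggregator (`aggregate = "vote"`) and the two agree on hard calls at 0.5.

Two further analyses interrogate a fitted model. `monte_carlo_stability()`
re-draws the unlabelled half of the working set many times, refits, and
reports the spread of accuracy and AUC — the package's desk-scale default
is 200 iterations, with the full 10,000 available by argument.
`stage_association()` regresses a correct-prediction indicator on
development stage (logistic regression, Preclinical as reference,
two-sided Wald p-values, likelihood-ratio fallback under separation),
asking whether advanced-stage targets are easier to recognise.

The boosting family deserves one implementation note: it is discrete
AdaBoost.M1 over depth-limited CART trees — stagewise minimisation of the
exponential loss, with `interaction_depth` as the tree depth and the
boosted margin mapped to a probability through the logistic link
$1/(1+e^{-2F})$.

## Interpretation

`feature_importance()` discretises each feature into `n_bins = 5`
equal-frequency bins with all zeros collapsed into one bin (without the
collapse, quantile binning degenerates on a mostly-zero feature), then
reports the chi-squared statistic of the bin × label table and the
information gain $H(y) - H(y\mid \text{bin})$ in bits. Neither method sees
directionality, and no feature is ever removed. `fit_inspection_tree()`
fits a CART tree and reports, per node, the split, predicted class,
per-class counts and percentage of observations — the same quantities one
reads off a plotted tree. Both are descriptive tools, not part of the
production classifier.

## Enrichment validation

`overlap_enrichment()` validates a nominated target set against an external
gene list (e.g. literature text-mining hits): working-set genes are removed
from both sets, a 2×2 table over a gene universe is built, and a two-sided
Fisher's exact test (minimum-likelihood convention, via R's exact
implementation) gives the p-value. The reported odds ratio is the sample
odds ratio $(ad)/(bc)$ — not the conditional MLE — because that is the
quantity whose permutation null is centred at 1; degenerate tables are
flagged rather than crashed on. The universe defaults to 19,000 genes,
roughly the human protein-coding complement; it is a parameter because no
canonical count exists. `permutation_null()` draws, per permutation, two
independent uniform random sets of the observed sizes and recomputes the
test — equivalent under the null to permuting labels, and directly
interpretable: the observed odds ratio is compared against a null
distribution with mean ≈ 1.

## The synthetic-data generator

Because the licensed inputs of a real analysis cannot be shipped, the
generator produces data with the statistical structure the method assumes:

* **Zero-inflated Beta scores.** For every (gene, disease, data type)
  triple a record exists with a class-dependent activation probability
  (defaults: 0.03 background everywhere; 0.12 for target genes on the three
  signal channels animal model, RNA expression, genetic association; 0.25
  on `known_drug`, making it a genuine leakage feature that the default
  feature configuration must exclude); active scores are Beta(3, 2) for
  targets on signal channels and Beta(1.2, 4) otherwise. The result is the
  sparse, mostly-near-zero matrix the method expects.
* **SCAR labelling.** A fixed fraction of genes (default 10%) are true
  targets; a uniform random half of them (default `labelled_fraction =
  0.5`) is observed as positive. Selection completely at random is the
  simplest contamination mechanism and the one the PU device implicitly
  assumes; nothing is known about the real labelling mechanism, so nothing
  more structured is modelled.
* **Stages and literature list.** Observed positives draw one (sometimes
  two) active stages uniformly; a small fraction of non-positives gets a
  failed-programme stage, exercising the exclusion rule. The literature
  list samples genes with weight `enrichment_factor` for true targets, so
  enrichment validation has a planted effect to find, and is exactly
  uniform at factor 1.
* **Diseases are i.i.d.** — no ontology structure, because indirect
  associations are removed before aggregation anyway; the
  `indirect_fraction` flag exists purely so the removal logic has work to
  do.

What the generator does *not* emulate: correlated evidence across diseases
or data types, therapeutic-area structure, the long-tailed per-source score
distributions of real platforms, or any biologically meaningful gene
identity. A passing test suite therefore demonstrates that the machinery is
correct and that the method behaves as theory predicts on data satisfying
its assumptions — not that any particular real dataset would yield the same
performance.

No quantitative sparsity or score distribution is published for the real
matrices, so the defaults were calibrated qualitatively once (sparse, most
values near zero, signal concentrated in the three channels) and are not
revisited. Tests that need a *stronger* or *graded* plant (e.g. the
tree-root recovery test, which requires animal model to dominate RNA
expression and genetic association) construct their own configurations in
the test helpers.

## Reproducibility and problem sizes

Every stochastic step takes a seed; `run_pipeline()` fans a single global
seed out into per-stage seeds through a fixed integer derivation (recorded
in the manifest), so stages can be reproduced independently and two runs
with the same seed produce byte-identical artefacts. Seeded draws are
wrapped so that the caller's RNG state is never disturbed.

The test suite and acceptance script run on deliberately moderate problem
sizes — synthetic universes of 250–3,000 genes, ensembles of 1–25 bags,
50-iteration stability loops, 2,000-permutation nulls — chosen so the whole
suite completes in well under a minute while leaving every statistical
assertion comfortably powered. The full-scale settings (100 bags, 10,000
iterations/permutations) remain the package defaults for analysis use.

## Known limitations

* Treating unlabelled as negative biases all PU-label-based metrics; the
  package quantifies the direction of the bias but does not correct for it
  (no class-prior estimation is attempted).
* Predictions are per gene, not per gene–indication pair; a gene strongly
  associated with one disease and a gene weakly associated with many can
  receive similar feature profiles.
* The stage-association analysis uses a plain logistic model with a
  likelihood-ratio fallback under separation; with very few genes per stage
  its p-values are approximate.
* The enrichment test conditions on set sizes and a user-supplied universe;
  a misjudged universe size shifts the odds ratio, which is why the
  permutation null (which shares the universe) is reported alongside.
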