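#' @keywords internal
"_PACKAGE"

## The seven evidence channels linking a gene to a disease, each scored in
## [0,1]. Five of them feed the design matrix; known_drug and literature are
## excluded by default (label leakage / reserved for validation).
OT_DATA_TYPES <- c(
  "affected_pathway", "animal_model", "genetic_association",
  "known_drug", "literature", "rna_expression", "somatic_mutation"
)

DEFAULT_FEATURE_TYPES <- c(
  "affected_pathway", "animal_model", "genetic_association",
  "rna_expression", "somatic_mutation"
)

## Development stages that define the positive label, in precedence order
## (least to most advanced).
POSITIVE_STAGES <- c(
  "Preclinical", "Clinical Trial", "Phase I Clinical Trial",
  "Phase II Clinical Trial", "Phase III Clinical Trial",
  "Pre-registration", "Registered", "Launched"
)

## Failed-programme categories: genes with only these stages stay unlabelled.
FAILED_STAGES <- c("Suspended", "Discontinued", "Withdrawn")

#' Evidence data-type vocabulary
#'
#' @return Character vector of the seven association data-type names.
#' @export
evidence_data_types <- function() OT_DATA_TYPES

#' Development-stage vocabularies
#'
#' @return For `positive_stages()`, the stages that define a target label, in
#'   precedence order (least to most advanced). For `failed_stages()`, the
#'   failed-programme categories excluded from the positive set.
#' @export
positive_stages <- function() POSITIVE_STAGES

#' @rdname positive_stages
#' @export
failed_stages <- function() FAILED_STAGES

## Derive a per-stage seed from the pipeline's global seed so that each stage
## is independently reproducible. Kept within 32-bit integer range.
derive_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 48271 + stage_index * 100003) %% 2147483647L)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)

as_label <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stopf("labels must be 0/1")
  y
}
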