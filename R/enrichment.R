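#' Overlap enrichment of a predicted gene set against a reference list
#'
#' Builds the 2x2 contingency table of membership in the predicted set vs
#' the reference list over a gene universe of given size (after removing the
#' exclusion set -- typically the training and test genes -- from both sets)
#' and assesses the overlap with a two-sided Fisher's exact test. The
#' reported odds ratio is the sample odds ratio (a*d)/(b*c) of the table; a
#' zero off-diagonal product is flagged and reported as `Inf`.
#'
#' @param predicted Character vector of predicted target gene ids.
#' @param reference Character vector of reference (e.g. literature) gene ids.
#' @param exclusions Gene ids removed from both sets before testing.
#' @param universe_size Total number of genes in the universe (default
#'   19,000, roughly the protein-coding complement).
#' @return An object of class `enrichment_result`: list with `table` (2x2
#'   matrix), `odds_ratio`, `odds_ratio_infinite` flag, `p_value`,
#'   `universe_size`, `overlap`.
#' @export
overlap_enrichment <- function(predicted, reference, exclusions = character(),
                               universe_size = 19000) {
  predicted <- setdiff(unique(as.character(predicted)), exclusions)
  reference <- setdiff(unique(as.character(reference)), exclusions)
  a <- length(intersect(predicted, reference))
  b <- length(predicted) - a
  cc <- length(reference) - a
  d <- universe_size - a - b - cc
  if (d < 0)
    stopf("universe_size (%d) smaller than the union of the sets (%d)",
          universe_size, a + b + cc)
  tab <- matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE,
                dimnames = list(predicted = c("yes", "no"),
                                reference = c("yes", "no")))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  infinite <- (b * cc) == 0
  or <- if (infinite) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * cc)
  structure(list(table = tab, odds_ratio = or,
                 odds_ratio_infinite = infinite,
                 p_value = min(p, 1), universe_size = universe_size,
                 overlap = a),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Gene-set overlap enrichment (universe:", x$universe_size, "genes)\n")
  print(x$table)
  cat(sprintf("odds ratio = %s, two-sided exact p = %.3g\n",
              if (x$odds_ratio_infinite) "Inf (degenerate table)"
              else formatC(x$odds_ratio, digits = 4),
              x$p_value))
  invisible(x)
}

#' Permutation null distribution of the overlap test
#'
#' Draws, for each permutation, two independent uniformly random gene sets of
#' the stated sizes from the universe and computes [overlap_enrichment()] on
#' them, yielding the null distribution of p-values and odds ratios against
#' which an observed enrichment can be judged. Under this null the mean odds
#' ratio is approximately 1. Each permutation draws set A then set B, in that
#' order, from the seeded RNG stream.
#'
#' @param predicted_size,reference_size Sizes of the two random sets.
#' @param universe_size Universe size.
#' @param n_permutations Number of permutations (default 10,000).
#' @param seed Integer seed.
#' @param compute_p Also compute the exact p per permutation (set `FALSE` to
#'   skip the test and return odds ratios only, which is much faster).
#' @return List with `per_permutation` (data frame of `odds_ratio`, and
#'   `p_value` when computed) and `summary` (means and sds).
#' @export
permutation_null <- function(predicted_size, reference_size,
                             universe_size = 19000, n_permutations = 10000,
                             seed = 1L, compute_p = TRUE) {
  if (predicted_size > universe_size || reference_size > universe_size)
    stopf("set sizes must not exceed universe_size")
  if (n_permutations < 1) stopf("n_permutations must be >= 1")
  ors <- numeric(n_permutations)
  ps <- if (compute_p) numeric(n_permutations) else NULL
  withr::with_seed(as.integer(seed), {
    member_a <- logical(universe_size)
    for (i in seq_len(n_permutations)) {
      set_a <- sample.int(universe_size, predicted_size)
      set_b <- sample.int(universe_size, reference_size)
      member_a[set_a] <- TRUE
      a <- sum(member_a[set_b])
      member_a[set_a] <- FALSE
      b <- predicted_size - a
      cc <- reference_size - a
      d <- universe_size - a - b - cc
      ors[i] <- if (b * cc == 0) Inf else (a * d) / (b * cc)
      if (compute_p)
        ps[i] <- stats::fisher.test(matrix(c(a, b, cc, d), 2,
                                           byrow = TRUE))$p.value
    }
  })
  per <- data.frame(odds_ratio = ors)
  if (compute_p) per$p_value <- pmin(ps, 1)
  summ <- c(mean_odds_ratio = mean(ors[is.finite(ors)]),
            sd_odds_ratio = stats::sd(ors[is.finite(ors)]))
  if (compute_p)
    summ <- c(summ, mean_p = mean(per$p_value), sd_p = stats::sd(per$p_value))
  list(per_permutation = per, summary = summ)
}
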