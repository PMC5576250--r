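test_that("record stream is a deterministic function of the seed and handles degenerate activation", {
  cfg <- synthetic_config(n_genes = 200, n_diseases = 10, seed = 42)
  g1 <- generate_evidence(cfg)
  g2 <- generate_evidence(cfg)
  expect_identical(g1$records, g2$records)
  expect_identical(g1$truth, g2$truth)

  off <- synthetic_config(n_genes = 50, n_diseases = 5,
                          activation_prob_target = 0,
                          activation_prob_background = 0, seed = 1)
  g0 <- generate_evidence(off)
  expect_identical(nrow(g0$records), 0L)
  m <- build_feature_matrix(g0$records, feature_config(),
                            universe = g0$truth$gene_id)
  expect_true(all(m == 0))
  expect_identical(nrow(m), 50L)
})

test_that("ground-truth and record counts agree with a brute-force recount", {
  cfg <- synthetic_config(n_genes = 1000, n_diseases = 20,
                          true_target_fraction = 0.1,
                          labelled_fraction = 0.5, seed = 9)
  gen <- generate_evidence(cfg)
  expect_identical(sum(gen$truth$true_target), 100L)
  expect_identical(sum(gen$truth$observed_positive), 50L)
  ## observed_positive implies true_target
  expect_true(all(gen$truth$true_target[gen$truth$observed_positive]))
  ## all record genes exist in the truth table, scores are valid
  expect_true(all(gen$records$gene %in% gen$truth$gene_id))
  expect_true(all(gen$records$score >= 0 & gen$records$score <= 1))
  expect_true(all(gen$records$datatype %in% evidence_data_types()))
})

test_that("indirect-association fraction lies within binomial 99% bounds", {
  cfg <- synthetic_config(n_genes = 800, n_diseases = 20,
                          indirect_fraction = 0.2, seed = 3)
  rec <- generate_evidence(cfg)$records
  phat <- mean(!rec$is_direct)
  half <- 2.576 * sqrt(0.2 * 0.8 / nrow(rec))
  expect_lt(abs(phat - 0.2), half + 1e-12)
})

test_that("stage table rows recount: positives always staged, failed stages only for non-positives", {
  cfg <- synthetic_config(n_genes = 500, n_diseases = 5,
                          true_target_fraction = 0.4,
                          labelled_fraction = 0.5, seed = 5)
  truth <- generate_evidence(cfg)$truth
  expect_identical(sum(truth$observed_positive), 100L)

  st0 <- generate_stage_table(truth, multi_stage_prob = 0,
                              failed_stage_fraction = 0, seed = 1)
  pos <- truth$gene_id[truth$observed_positive]
  expect_setequal(st0$gene, pos)
  expect_identical(nrow(st0), 100L)
  expect_true(all(st0$stage %in% positive_stages()))

  st <- generate_stage_table(truth, multi_stage_prob = 0.3,
                             failed_stage_fraction = 0.1, seed = 2)
  pos_rows <- st[st$gene %in% pos, ]
  extra <- nrow(pos_rows) - length(pos)
  expect_gte(extra, 0)
  ## extra-stage count is Binomial(100, 0.3): 99% bounds
  expect_lt(abs(extra / 100 - 0.3), 2.576 * sqrt(0.3 * 0.7 / 100) + 1e-12)
  ## a multi-stage gene never repeats a stage
  expect_false(any(duplicated(pos_rows)))
  neg_rows <- st[!(st$gene %in% pos), ]
  expect_true(all(neg_rows$stage %in% failed_stages()))
  expect_false(any(pos_rows$stage %in% failed_stages()))
})

test_that("literature list respects size, errors and enrichment weighting", {
  cfg <- synthetic_config(n_genes = 200, n_diseases = 5,
                          true_target_fraction = 0.25, seed = 8)
  truth <- generate_evidence(cfg)$truth
  expect_identical(generate_literature_list(truth, 1, 0, seed = 1), character())
  expect_error(generate_literature_list(truth, 1, 300, seed = 1), "exceeds")
  expect_error(generate_literature_list(truth, 0.5, 10, seed = 1), ">= 1")

  ## enrichment_factor = 1: target fraction in the list is that of the genome
  frac1 <- mean(vapply(1:40, function(s) {
    l <- generate_literature_list(truth, 1, 50, seed = s)
    mean(l %in% truth$gene_id[truth$true_target])
  }, numeric(1)))
  expect_lt(abs(frac1 - 0.25), 0.03)

  ## enrichment_factor = 10, size = n/4: realised target fraction matches an
  ## independent sequential weighted-sampling oracle within binomial error
  oracle_draw <- function(seed) {
    withr::with_seed(seed + 10000, {
      ids <- truth$gene_id
      w <- ifelse(truth$true_target, 10, 1)
      out <- character(50)
      for (i in 1:50) {
        j <- sample.int(length(ids), 1, prob = w)
        out[i] <- ids[j]
        ids <- ids[-j]; w <- w[-j]
      }
      out
    })
  }
  frac_imp <- mean(vapply(1:40, function(s)
    mean(generate_literature_list(truth, 10, 50, seed = s) %in%
           truth$gene_id[truth$true_target]), numeric(1)))
  frac_orc <- mean(vapply(1:40, function(s)
    mean(oracle_draw(s) %in% truth$gene_id[truth$true_target]), numeric(1)))
  se <- sqrt(frac_orc * (1 - frac_orc) / (40 * 50))
  expect_lt(abs(frac_imp - frac_orc), 4 * se)
})

test_that("with all class signal removed, downstream classification is at chance against ground truth", {
  aucs <- vapply(1:20, function(r) {
    d <- make_pu_data(null_config(seed = 200 + r))
    fit <- pu_bag(part_x(d, "train"), part_y(d, "train"),
                  base_learner("decision_tree"), n_bags = 1,
                  bootstrap = FALSE, seed = 1)
    ids <- d$partition$gene_id[d$partition$partition == "prediction"]
    roc_auc(predict(fit, d$features[ids, , drop = FALSE]), truth_of(d, ids))
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})
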