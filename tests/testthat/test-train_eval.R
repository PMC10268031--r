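# A dataset shell with the shape of a real association screen: IDs and
# positives only, never parsed (negative sampling and folding do not need
# chemistry).
make_shell_dataset <- function(n_mol, n_mir, n_pos, seed = 1) {
  set.seed(seed)
  molecules <- setNames(rep("C", n_mol), sprintf("SM%04d", seq_len(n_mol)))
  mirnas <- setNames(rep("AUGGC", n_mir), sprintf("miR%04d", seq_len(n_mir)))
  idx <- sample(n_mol * n_mir, n_pos)
  positives <- data.frame(
    molecule_id = names(molecules)[(idx - 1) %/% n_mir + 1],
    mirna_id = names(mirnas)[(idx - 1) %% n_mir + 1],
    stringsAsFactors = FALSE
  )
  association_dataset(molecules, mirnas, positives)
}

test_that("negative sampling hits the requested count and never collides", {
  ds <- make_shell_dataset(831, 541, 664)
  out <- sample_negatives(ds, ratio = 1, seed = 2)
  expect_equal(nrow(out$negatives), 664L)
  expect_equal(nrow(merge(out$negatives, out$positives)), 0L)
  # candidate space arithmetic: 831 * 541 - 664 unlabeled pairs remain
  expect_error(sample_negatives(ds, ratio = (831 * 541 - 664 + 1) / 664,
                                seed = 2), "448907")
  out2 <- sample_negatives(ds, ratio = 1, seed = 2)
  expect_identical(out2$negatives, out$negatives)  # seed determinism
  out3 <- sample_negatives(ds, ratio = 1, seed = 3)
  expect_false(identical(out3$negatives, out$negatives))
})

test_that("pairwise folds are balanced and partition the labeled pairs", {
  ds <- sample_negatives(make_shell_dataset(831, 541, 332), ratio = 1,
                         seed = 5)
  ds <- make_folds(ds, k = 5, protocol = "pairwise", seed = 5)
  sizes <- as.integer(table(ds$labeled$fold))
  expect_equal(sort(sizes), c(132L, 133L, 133L, 133L, 133L))  # 664 pairs
  expect_equal(nrow(ds$labeled), 664L)
  expect_false(any(duplicated(
    paste(ds$labeled$molecule_id, ds$labeled$mirna_id))))
})

test_that("molecule folds hold out every pair of one molecule", {
  ds <- sample_negatives(make_shell_dataset(12, 20, 30), ratio = 1, seed = 6)
  ds <- suppressWarnings(make_folds(ds, protocol = "molecule", seed = 6))
  for (f in unique(ds$labeled$fold)) {
    held <- unique(ds$labeled$molecule_id[ds$labeled$fold == f])
    expect_equal(length(held), 1L)
    expect_false(held %in% ds$labeled$molecule_id[ds$labeled$fold != f])
  }
})

test_that("molecules without labeled pairs trigger a warning, not an error", {
  ds <- make_shell_dataset(12, 20, 4)
  ds <- sample_negatives(ds, ratio = 1, seed = 7)
  expect_warning(make_folds(ds, protocol = "molecule", seed = 7),
                 "no labeled pairs")
})

test_that("roc_auc reproduces known values", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  # worked 4-point example: 3 of 4 positive/negative pairs concordant
  expect_equal(roc_auc(c(0.9, 0.4, 0.8, 0.2), c(1, 1, 0, 0))$auc, 0.75)
  expect_equal(roc_auc(rep(0.3, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("the ROC curve is a monotone path from (0,0) to (1,1)", {
  set.seed(14)
  r <- roc_auc(rnorm(50), rep(c(0, 1), 25))
  expect_equal(r$roc$fpr[1], 0)
  expect_equal(r$roc$tpr[1], 0)
  expect_equal(r$roc$fpr[nrow(r$roc)], 1)
  expect_equal(r$roc$tpr[nrow(r$roc)], 1)
  expect_true(all(diff(r$roc$fpr) >= 0))
  expect_true(all(diff(r$roc$tpr) >= 0))
  # trapezoidal area under the curve equals the rank-based AUC
  area <- sum(diff(r$roc$fpr) * (head(r$roc$tpr, -1) + tail(r$roc$tpr, -1)) / 2)
  expect_equal(area, r$auc, tolerance = 1e-12)
})

test_that("roc_auc matches brute-force concordance counting on fuzzed sets", {
  set.seed(15)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(round(rnorm(n), sample(0:2, 1)))  # force ties often
    expect_equal(roc_auc(scores, labels)$auc,
                 brute_force_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("roc_auc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(16)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, 0.4)
  expect_equal(roc_auc(scores, labels)$auc,
               as.numeric(pROC::auc(labels, scores, direction = "<",
                                    levels = c(0, 1), quiet = TRUE)),
               tolerance = 1e-12)
})

test_that("candidate ranking sorts by score with lexicographic tie-break", {
  syn <- generate_synthetic(synthetic_spec(n_molecules = 5, n_mirnas = 6,
                                           seed = 17))
  ds <- sample_negatives(syn$dataset, 1, seed = 17)
  m <- train(ds, molmir_config(epochs = 2))
  rk <- rank_candidates(m, ds, top_k = 1000)
  n_cand <- 30 - sum(m$train_pairs$label)
  expect_equal(nrow(rk), n_cand)  # clamped to the candidate count
  expect_equal(rk$rank, seq_len(n_cand))
  expect_true(all(diff(rk$score) <= 0))
  # agreement with an independent sort of the same scores
  pr <- predict(m, rk[, c("molecule_id", "mirna_id")], ds)
  ord <- order(-pr$prob, pr$molecule_id, pr$mirna_id)
  expect_equal(pr$prob[ord], rk$score)
  # training positives are excluded from the candidate list
  pos <- m$train_pairs[m$train_pairs$label == 1, ]
  expect_equal(nrow(merge(rk, pos[, c("molecule_id", "mirna_id")])), 0L)
  expect_equal(nrow(rank_candidates(m, ds, top_k = 3)), 3L)
})

test_that("cross-validation scores every labeled pair exactly once", {
  syn <- generate_synthetic(synthetic_spec(n_molecules = 8, n_mirnas = 10,
                                           seed = 18))
  ds <- sample_negatives(syn$dataset, 1, seed = 18)
  cv <- cross_validate(ds, molmir_config(epochs = 1), k = 3)
  expect_equal(cv$k, 3L)
  expect_true(all(cv$predictions$prob >= 0 & cv$predictions$prob <= 1))
  lp <- molmiR:::labeled_pairs(ds)
  expect_setequal(paste(cv$predictions$molecule_id, cv$predictions$mirna_id),
                  paste(lp$molecule_id, lp$mirna_id))
  expect_equal(nrow(cv$predictions), nrow(lp))
})
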