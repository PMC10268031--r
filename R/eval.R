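#' Sample negative pairs from the unlabeled candidate space
#'
#' Known association lists record only positives; a binary classifier
#' additionally needs label-0 pairs. Negatives are drawn uniformly without
#' replacement from all molecule x miRNA pairs that are not positives.
#'
#' @param dataset An [association_dataset()].
#' @param ratio Negatives per positive (default 1).
#' @param seed Integer seed; the same seed always yields the same sample.
#' @return The dataset with its `negatives` slot populated.
#' @export
sample_negatives <- function(dataset, ratio = 1, seed = 1L) {
  stopifnot(inherits(dataset, "association_dataset"), ratio > 0)
  n_mol <- length(dataset$molecules)
  n_mir <- length(dataset$mirnas)
  total <- n_mol * n_mir
  pos_idx <- (match(dataset$positives$molecule_id, names(dataset$molecules)) - 1L) *
    n_mir + match(dataset$positives$mirna_id, names(dataset$mirnas))
  n_neg <- round(ratio * nrow(dataset$positives))
  candidates <- total - nrow(dataset$positives)
  if (n_neg > candidates) {
    stop("requested ", n_neg, " negatives but only ", candidates,
         " unlabeled pairs exist", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- sample(setdiff(seq_len(total), pos_idx), n_neg)
  dataset$negatives <- data.frame(
    molecule_id = names(dataset$molecules)[(idx - 1L) %/% n_mir + 1L],
    mirna_id = names(dataset$mirnas)[(idx - 1L) %% n_mir + 1L],
    stringsAsFactors = FALSE
  )
  dataset$labeled <- NULL
  dataset
}

#' Assign cross-validation folds to the labeled pairs
#'
#' Two protocols:
#' \describe{
#'   \item{pairwise}{the labeled pairs are split uniformly at random into
#'     `k` folds of near-equal size (sizes differ by at most one).}
#'   \item{molecule}{one fold per molecule: all labeled pairs of a
#'     molecule are held out together, so the held-out molecule is
#'     entirely unseen during training (leave-one-molecule-out; simulates
#'     prediction for a new drug).}
#' }
#'
#' @param dataset An [association_dataset()] with negatives populated.
#' @param k Number of folds (pairwise protocol; `k >= 2`).
#' @param protocol `"pairwise"` or `"molecule"`.
#' @param seed Integer seed for the random split.
#' @return The dataset with a `labeled` data.frame (`molecule_id`,
#'   `mirna_id`, `label`, `fold`) attached; folds partition the labeled
#'   pairs.
#' @export
make_folds <- function(dataset, k = 5L, protocol = c("pairwise", "molecule"),
                       seed = 1L) {
  protocol <- match.arg(protocol)
  pairs <- labeled_pairs(dataset)
  if (nrow(pairs) == 0L) stop("no labeled pairs to fold", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (protocol == "pairwise") {
    if (k < 2L) stop("pairwise protocol needs k >= 2", call. = FALSE)
    pairs$fold <- sample(rep_len(seq_len(k), nrow(pairs)))
  } else {
    unused <- setdiff(names(dataset$molecules), unique(pairs$molecule_id))
    if (length(unused)) {
      warning(length(unused),
              " molecule(s) have no labeled pairs and are skipped: ",
              paste(utils::head(unused, 5L), collapse = ", "),
              call. = FALSE)
    }
    mols <- unique(pairs$molecule_id)
    pairs$fold <- match(pairs$molecule_id, mols)
  }
  dataset$labeled <- pairs
  dataset
}

#' ROC curve and AUC from scores and binary labels
#'
#' AUC is computed by the rank (Mann-Whitney) formulation -- the
#' probability that a random positive outscores a random negative, with
#' ties counted half -- which equals the trapezoidal area under the ROC
#' curve built from the same scores.
#'
#' @param scores Numeric scores, higher = more likely positive.
#' @param labels Binary labels (0/1), both classes present.
#' @return List with `auc` and `roc`, a data.frame of (`fpr`, `tpr`)
#'   points from (0,0) to (1,1), one step per distinct score.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be 0/1", call. = FALSE)
  }
  P <- sum(labels == 1L)
  N <- sum(labels == 0L)
  if (P == 0L || N == 0L) {
    stop("both classes must be present to compute a ROC curve",
         call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - P * (P + 1) / 2) / (P * N)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # one ROC vertex per distinct threshold; ties advance jointly
  last <- cumsum(rle(s)$lengths)
  tpr <- c(0, cumsum(l)[last] / P)
  fpr <- c(0, cumsum(1 - l)[last] / N)
  list(auc = auc, roc = data.frame(fpr = fpr, tpr = tpr))
}

#' Cross-validate the model on a dataset
#'
#' Runs the requested protocol (see [make_folds()]): for each fold, a
#' model is trained from scratch on the remaining labeled pairs and scored
#' on the held-out pairs. Training negatives are redrawn once per fold
#' from the pairs that are neither positives nor held out, so held-out
#' information never enters training; held-out negatives are the
#' dataset-level sample.
#'
#' @param dataset An [association_dataset()]; negatives are sampled at
#'   `config$ratio` if absent.
#' @param config A [molmir_config()].
#' @param protocol `"pairwise"` (k-fold over pairs) or `"molecule"`
#'   (leave-one-molecule-out).
#' @param k Fold count for the pairwise protocol.
#' @param seed Seed governing negative sampling, fold assignment and
#'   per-fold training.
#' @param verbose Print per-fold progress.
#' @return An object of class `molmir_eval`: `protocol`, `fold_auc`
#'   (NA where a held-out fold has a single class), `mean_auc` (mean over
#'   defined folds), pooled `auc` and `roc` over all held-out predictions,
#'   `predictions`, and `seed`.
#' @export
cross_validate <- function(dataset, config = molmir_config(),
                           protocol = c("pairwise", "molecule"), k = 5L,
                           seed = config$seed, verbose = FALSE) {
  protocol <- match.arg(protocol)
  if (nrow(dataset$negatives) == 0L) {
    dataset <- sample_negatives(dataset, ratio = config$ratio, seed = seed)
  }
  dataset <- make_folds(dataset, k = k, protocol = protocol, seed = seed)
  labeled <- dataset$labeled
  folds <- sort(unique(labeled$fold))
  n_mol <- length(dataset$molecules)
  n_mir <- length(dataset$mirnas)
  preds <- vector("list", length(folds))
  fold_auc <- rep(NA_real_, length(folds))
  for (fi in seq_along(folds)) {
    f <- folds[fi]
    test <- labeled[labeled$fold == f, , drop = FALSE]
    train_pos <- labeled[labeled$fold != f & labeled$label == 1L, ,
                         drop = FALSE]
    if (nrow(train_pos) == 0L) {
      stop("fold ", f, " leaves no positive training pairs", call. = FALSE)
    }
    # redraw training negatives outside positives and the held-out fold
    excl <- c(.pair_key(labeled$molecule_id[labeled$label == 1L],
                        labeled$mirna_id[labeled$label == 1L]),
              .pair_key(test$molecule_id, test$mirna_id))
    grid_mol <- rep(names(dataset$molecules), each = n_mir)
    grid_mir <- rep(names(dataset$mirnas), times = n_mol)
    free <- !(.pair_key(grid_mol, grid_mir) %in% excl)
    n_neg <- min(round(config$ratio * nrow(train_pos)), sum(free))
    old <- .Random.seed_save()
    set.seed(seed + f)
    pick <- sample(which(free), n_neg)
    .Random.seed_restore(old)
    train_pairs <- data.frame(
      molecule_id = c(train_pos$molecule_id, grid_mol[pick]),
      mirna_id = c(train_pos$mirna_id, grid_mir[pick]),
      label = rep(c(1L, 0L), c(nrow(train_pos), n_neg)),
      stringsAsFactors = FALSE
    )
    fold_config <- config
    fold_config$seed <- config$seed + f
    model <- train(dataset, fold_config, pairs = train_pairs)
    pr <- predict(model, test, dataset)
    pr$label <- test$label
    pr$fold <- f
    preds[[fi]] <- pr
    if (length(unique(test$label)) == 2L) {
      fold_auc[fi] <- roc_auc(pr$prob, test$label)$auc
    }
    if (verbose) {
      message(sprintf("fold %d/%d  held-out n=%d  AUC=%s", fi,
                      length(folds), nrow(test),
                      ifelse(is.na(fold_auc[fi]), "NA",
                             sprintf("%.3f", fold_auc[fi]))))
    }
  }
  predictions <- do.call(rbind, preds)
  pooled <- roc_auc(predictions$prob, predictions$label)
  structure(list(protocol = protocol, k = length(folds),
                 fold_auc = fold_auc,
                 mean_auc = mean(fold_auc, na.rm = TRUE),
                 auc = pooled$auc, roc = pooled$roc,
                 predictions = predictions, seed = seed),
            class = "molmir_eval")
}

#' @export
print.molmir_eval <- function(x, ...) {
  cat("<molmir_eval>", x$protocol, "protocol,", x$k, "folds\n")
  cat("  mean fold AUC:", format(x$mean_auc, digits = 4),
      "| pooled AUC:", format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' Rank candidate molecule-miRNA pairs by predicted probability
#'
#' Scores every pair outside the training positives and returns the top
#' candidates in descending probability; ties are broken by
#' (molecule_id, mirna_id) lexicographic order so rankings are
#' reproducible.
#'
#' @param model A trained `molmir_model`.
#' @param dataset The [association_dataset()].
#' @param top_k Number of candidates to return (clamped to the candidate
#'   count).
#' @return data.frame `rank`, `molecule_id`, `mirna_id`, `score`.
#' @export
rank_candidates <- function(model, dataset, top_k = 30L) {
  n_mir <- length(dataset$mirnas)
  grid <- data.frame(
    molecule_id = rep(names(dataset$molecules), each = n_mir),
    mirna_id = rep(names(dataset$mirnas), times = length(dataset$molecules)),
    stringsAsFactors = FALSE
  )
  trained_pos <- model$train_pairs[model$train_pairs$label == 1L, ]
  keep <- !(.pair_key(grid$molecule_id, grid$mirna_id) %in%
              .pair_key(trained_pos$molecule_id, trained_pos$mirna_id))
  cand <- grid[keep, , drop = FALSE]
  pr <- predict(model, cand, dataset)
  ord <- order(-pr$prob, pr$molecule_id, pr$mirna_id)
  pr <- pr[ord, , drop = FALSE]
  top_k <- min(top_k, nrow(pr))
  out <- data.frame(rank = seq_len(top_k),
                    molecule_id = pr$molecule_id[seq_len(top_k)],
                    mirna_id = pr$mirna_id[seq_len(top_k)],
                    score = pr$prob[seq_len(top_k)],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
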