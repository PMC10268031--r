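#' Assemble an association dataset
#'
#' Binds together a molecule table (SMILES), a set of miRNA sequences and
#' the labeled pair lists. Molecules are stored as SMILES and parsed to
#' graphs lazily when a model needs them.
#'
#' @param molecules Named character vector of SMILES (names = molecule IDs).
#' @param mirnas Named character vector of RNA sequences (names = miRNA IDs).
#' @param positives data.frame with `molecule_id`, `mirna_id` (label 1).
#' @param negatives Optional data.frame of label-0 pairs (default: none; see
#'   [sample_negatives()]).
#' @return An object of class `association_dataset`.
#' @export
association_dataset <- function(molecules, mirnas, positives,
                                negatives = NULL) {
  stopifnot(is.character(molecules), !is.null(names(molecules)),
            is.character(mirnas), !is.null(names(mirnas)))
  if (is.null(negatives)) {
    negatives <- data.frame(molecule_id = character(0),
                            mirna_id = character(0),
                            stringsAsFactors = FALSE)
  }
  .check_pairs <- function(p, what) {
    stopifnot(all(c("molecule_id", "mirna_id") %in% names(p)))
    miss_m <- setdiff(p$molecule_id, names(molecules))
    miss_s <- setdiff(p$mirna_id, names(mirnas))
    if (length(miss_m) || length(miss_s)) {
      stop(what, " reference unknown IDs: ",
           paste(c(miss_m, miss_s), collapse = ", "), call. = FALSE)
    }
    p[, c("molecule_id", "mirna_id")]
  }
  positives <- .check_pairs(positives, "positive pairs")
  negatives <- .check_pairs(negatives, "negative pairs")
  if (nrow(merge(positives, negatives))) {
    stop("positive and negative pair sets overlap", call. = FALSE)
  }
  structure(list(molecules = molecules, mirnas = mirnas,
                 positives = positives, negatives = negatives,
                 labeled = NULL),
            class = "association_dataset")
}

#' @export
print.association_dataset <- function(x, ...) {
  cat("<association_dataset>", length(x$molecules), "molecules x",
      length(x$mirnas), "miRNAs |", nrow(x$positives), "positives,",
      nrow(x$negatives), "negatives\n")
  invisible(x)
}

.pair_key <- function(mol, mir) paste(mol, mir, sep = "\r")

# All labeled pairs of a dataset as molecule_id / mirna_id / label.
labeled_pairs <- function(dataset) {
  pos <- dataset$positives
  neg <- dataset$negatives
  data.frame(
    molecule_id = c(pos$molecule_id, neg$molecule_id),
    mirna_id = c(pos$mirna_id, neg$mirna_id),
    label = rep(c(1L, 0L), c(nrow(pos), nrow(neg))),
    stringsAsFactors = FALSE
  )
}

# Parse + fingerprint every molecule in `ids`, growing `vocab`.
.prepare_molecules <- function(dataset, ids, config, vocab) {
  out <- vector("list", length(ids))
  names(out) <- ids
  for (id in ids) {
    g <- parse_smiles(dataset$molecules[[id]],
                      strip_hydrogens = config$strip_hydrogens,
                      molecule_id = id)
    out[[id]] <- fingerprint_graph(g, r = config$r, vocab = vocab)
  }
  out
}

.prepare_sequences <- function(dataset, ids, config) {
  out <- vector("list", length(ids))
  names(out) <- ids
  for (id in ids) {
    out[[id]] <- tokenize(dataset$mirnas[[id]], n = config$n, mirna_id = id)
  }
  out
}

#' Train the association model
#'
#' Builds the fingerprint vocabulary from the training molecules
#' (then freezes it, so unseen chemistry at prediction time maps to the
#' unknown fingerprint), tokenizes the training miRNAs, initializes all
#' tensors, and minimizes the cross-entropy of the softmax association
#' probabilities against the pair labels by per-pair stochastic updates
#' (Adam by default, momentum SGD via `config$optimizer`). Deterministic
#' for a fixed `config$seed` and single-threaded BLAS.
#'
#' @param dataset An [association_dataset()] whose positives (and
#'   negatives, see [sample_negatives()]) define the training pairs.
#' @param config A [molmir_config()].
#' @param pairs Optional data.frame `molecule_id`, `mirna_id`, `label`
#'   overriding the dataset's labeled pairs (used by cross-validation).
#' @param verbose Print per-epoch loss.
#' @return An object of class `molmir_model`: the learned parameters,
#'   frozen vocabulary, resolved configuration, the fingerprinted training
#'   graphs, and a training log (`data.frame` epoch/loss).
#' @export
train <- function(dataset, config = molmir_config(), pairs = NULL,
                  verbose = FALSE) {
  stopifnot(inherits(dataset, "association_dataset"))
  if (is.null(pairs)) pairs <- labeled_pairs(dataset)
  if (nrow(pairs) == 0L) stop("no labeled training pairs", call. = FALSE)
  if (!all(pairs$label %in% c(0L, 1L))) {
    stop("pair labels must be 0 or 1", call. = FALSE)
  }

  vocab <- fingerprint_vocab(r = config$r)
  graphs <- .prepare_molecules(dataset, unique(pairs$molecule_id), config,
                               vocab)
  freeze_vocab(vocab)
  tokens <- .prepare_sequences(dataset, unique(pairs$mirna_id), config)

  params <- init_model_params(vocab$n_vertex, vocab$n_edge,
                              length(kmer_vocabulary(config$n)),
                              config, seed = config$seed)
  opt <- .optimizer_init(params, config)
  n <- nrow(pairs)
  mol_id <- pairs$molecule_id
  mir_id <- pairs$mirna_id
  lab <- pairs$label
  log <- data.frame(epoch = integer(0), loss = numeric(0))
  set.seed(config$seed)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    total <- 0
    for (idx in ord) {
      fw <- forward_pair(graphs[[mol_id[idx]]], tokens[[mir_id[idx]]],
                         params, config, keep = TRUE)
      loss <- pair_loss(fw$prob, lab[idx])
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", epoch, ", pair ",
             mol_id[idx], "/", mir_id[idx], call. = FALSE)
      }
      total <- total + loss
      gr <- backward_pair(fw, lab[idx], params, config)
      params <- .optimizer_step(opt, params, gr, config)
    }
    log <- rbind(log, data.frame(epoch = epoch, loss = total / n))
    if (verbose) {
      message(sprintf("epoch %3d  mean loss %.4f", epoch, total / n))
    }
  }
  structure(list(params = params, vocab = vocab, config = config,
                 graphs = graphs, tokens = tokens,
                 train_pairs = pairs, log = log),
            class = "molmir_model")
}

#' @export
print.molmir_model <- function(x, ...) {
  cat("<molmir_model> d =", x$config$d, "| trained on",
      nrow(x$train_pairs), "pairs (", sum(x$train_pairs$label), "positive )\n")
  if (nrow(x$log)) {
    cat("  final mean training loss:",
        format(x$log$loss[nrow(x$log)], digits = 4), "\n")
  }
  invisible(x)
}

#' Predict association probabilities for molecule-miRNA pairs
#'
#' Molecules never seen in training are parsed and fingerprinted against
#' the model's frozen vocabulary, so novel neighborhood signatures map to
#' the unknown fingerprint and prediction degrades gracefully instead of
#' failing (the cold-start path).
#'
#' @param object A trained `molmir_model`.
#' @param pairs data.frame with `molecule_id` and `mirna_id`.
#' @param dataset The [association_dataset()] resolving the IDs.
#' @param with_attention Attach the per-window attention weights of each
#'   pair as a list column `attention`.
#' @param ... Unused.
#' @return data.frame `molecule_id`, `mirna_id`, `prob` (probability of
#'   association, in `[0, 1]`), plus `attention` if requested.
#' @export
predict.molmir_model <- function(object, pairs, dataset,
                                 with_attention = FALSE, ...) {
  config <- object$config
  graphs <- object$graphs
  new_mols <- setdiff(unique(pairs$molecule_id), names(graphs))
  if (length(new_mols)) {
    graphs <- c(graphs,
                .prepare_molecules(dataset, new_mols, config, object$vocab))
  }
  tokens <- object$tokens
  new_seqs <- setdiff(unique(pairs$mirna_id), names(tokens))
  if (length(new_seqs)) {
    tokens <- c(tokens, .prepare_sequences(dataset, new_seqs, config))
  }
  n <- nrow(pairs)
  prob <- numeric(n)
  att <- if (with_attention) vector("list", n)
  for (i in seq_len(n)) {
    fw <- forward_pair(graphs[[pairs$molecule_id[i]]],
                       tokens[[pairs$mirna_id[i]]],
                       object$params, config)
    prob[i] <- fw$prob[2L]
    if (with_attention) att[[i]] <- fw$alpha
  }
  out <- data.frame(molecule_id = pairs$molecule_id,
                    mirna_id = pairs$mirna_id, prob = prob,
                    stringsAsFactors = FALSE)
  if (with_attention) out$attention <- att
  out
}

# Optimizer state lives in an environment so steps mutate in place.
.optimizer_init <- function(params, config) {
  e <- new.env(parent = emptyenv())
  e$t <- 0
  if (config$optimizer == "adam") {
    e$m <- .zero_like(params)
    e$v <- .zero_like(params)
  } else {
    e$vel <- .zero_like(params)
  }
  e
}

.optimizer_step <- function(opt, params, gr, config) {
  pn <- names(params)
  if (config$optimizer == "adam") {
    opt$t <- opt$t + 1
    b1 <- 0.9
    b2 <- 0.999
    eps <- 1e-8
    corr1 <- 1 - b1^opt$t
    corr2 <- 1 - b2^opt$t
    for (nm in pn) {
      opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * gr[[nm]]
      opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * gr[[nm]]^2
      params[[nm]] <- params[[nm]] - config$lr *
        (opt$m[[nm]] / corr1) / (sqrt(opt$v[[nm]] / corr2) + eps)
    }
  } else {
    for (nm in pn) {
      opt$vel[[nm]] <- config$momentum * opt$vel[[nm]] - config$lr * gr[[nm]]
      params[[nm]] <- params[[nm]] + opt$vel[[nm]]
    }
  }
  params
}
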