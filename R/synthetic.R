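# Fragment grammar for generated molecules. Fragments are concatenated as
# SMILES strings, which stays parseable because every fragment starts and
# ends at an atom with a free valence. The signal fragments are the only
# source of nitrogen.
.default_grammar <- list(
  background = c("C", "CC", "CCC", "CO", "CCO", "CC(C)O", "C=CC",
                 "c1ccccc1", "CC(=O)O"),
  signal = c("N", "CN", "CCN", "c1ccncc1")
)

#' Specification of a planted-signal synthetic dataset
#'
#' The generator emulates the shape of a molecule/miRNA association screen
#' while planting a recoverable decision rule: a pair is truly associated
#' iff the molecule contains at least one nitrogen atom AND the miRNA
#' sequence contains the motif. Both signals are detectable by the two
#' encoders (nitrogen changes atom-level fingerprints; the motif changes
#' 3-mer windows), so a working pipeline must be able to learn the rule.
#'
#' @param n_molecules,n_mirnas Entity counts (defaults 40 and 60).
#' @param seq_len_range Min/max sequence length in bases (default 19-25,
#'   the mature miRNA range).
#' @param molecule_grammar List with `background` and `signal` SMILES
#'   fragment pools; signal fragments carry the nitrogen signal.
#' @param motif Sequence motif of the positive rule (default `"AUGGC"`).
#' @param signal_prob Probability that a molecule receives a signal
#'   fragment / that a sequence receives a planted motif (default 0.5).
#' @param label_noise Probability that a pair's label is flipped
#'   (default 0.05).
#' @param seed Integer seed; generation is fully reproducible.
#' @return A classed list (`synthetic_spec`).
#' @export
synthetic_spec <- function(n_molecules = 40L, n_mirnas = 60L,
                           seq_len_range = c(19L, 25L),
                           molecule_grammar = .default_grammar,
                           motif = "AUGGC", signal_prob = 0.5,
                           label_noise = 0.05, seed = 1L) {
  stopifnot(n_molecules >= 1, n_mirnas >= 1,
            length(seq_len_range) == 2L,
            seq_len_range[1] >= 1, seq_len_range[1] <= seq_len_range[2],
            label_noise >= 0, label_noise <= 1,
            signal_prob >= 0, signal_prob <= 1,
            is.list(molecule_grammar),
            all(c("background", "signal") %in% names(molecule_grammar)))
  if (!grepl("^[ACGU]+$", motif)) {
    stop("motif must be a non-empty string over A/C/G/U", call. = FALSE)
  }
  if (nchar(motif) > seq_len_range[1]) {
    stop("motif (", nchar(motif), " bases) is longer than the minimum ",
         "sequence length (", seq_len_range[1], ")", call. = FALSE)
  }
  if (any(grepl("N|n(?![a-z])", molecule_grammar$background, perl = TRUE))) {
    stop("background fragments must be nitrogen-free", call. = FALSE)
  }
  structure(list(n_molecules = as.integer(n_molecules),
                 n_mirnas = as.integer(n_mirnas),
                 seq_len_range = as.integer(seq_len_range),
                 molecule_grammar = molecule_grammar,
                 motif = motif, signal_prob = signal_prob,
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "synthetic_spec")
}

.contains_nitrogen <- function(graph) {
  any(graph$atoms$symbol == "N")
}

#' Generate a planted-signal synthetic dataset
#'
#' Molecules are composed from the fragment grammar (one or two background
#' fragments, plus one nitrogen-bearing signal fragment with probability
#' `signal_prob`); sequences are i.i.d. uniform bases with the motif
#' overwritten at a uniform random position with probability
#' `signal_prob`. Ground-truth labels apply the planted rule to the
#' generated artifacts themselves (a motif arising by chance counts), then
#' each label is independently flipped with probability `label_noise`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with
#'   \describe{
#'     \item{dataset}{an [association_dataset()] whose positives are the
#'       label-1 pairs (negatives left empty for [sample_negatives()]);}
#'     \item{labels}{data.frame of all pairs with `label` (noisy) and
#'       `truth` (the rule's value before noise);}
#'     \item{spec}{the input spec.}
#'   }
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  mol_ids <- sprintf("SM%03d", seq_len(spec$n_molecules))
  smiles <- character(spec$n_molecules)
  has_n <- logical(spec$n_molecules)
  for (i in seq_len(spec$n_molecules)) {
    frags <- sample(spec$molecule_grammar$background,
                    sample(1:2, 1L), replace = TRUE)
    if (stats::runif(1) < spec$signal_prob) {
      sig <- sample(spec$molecule_grammar$signal, 1L)
      pos <- sample(length(frags) + 1L, 1L)
      frags <- append(frags, sig, after = pos - 1L)
    }
    smiles[i] <- paste(frags, collapse = "")
  }
  names(smiles) <- mol_ids
  graphs <- lapply(mol_ids, function(id) {
    parse_smiles(smiles[[id]], molecule_id = id)
  })
  has_n <- vapply(graphs, .contains_nitrogen, logical(1))

  mir_ids <- sprintf("miR%03d", seq_len(spec$n_mirnas))
  lens <- sample(seq.int(spec$seq_len_range[1], spec$seq_len_range[2]),
                 spec$n_mirnas, replace = TRUE)
  mlen <- nchar(spec$motif)
  seqs <- vapply(seq_len(spec$n_mirnas), function(i) {
    s <- paste(sample(RNA_BASES, lens[i], replace = TRUE), collapse = "")
    if (stats::runif(1) < spec$signal_prob) {
      at <- sample(lens[i] - mlen + 1L, 1L)
      substr(s, at, at + mlen - 1L) <- spec$motif
    }
    s
  }, "")
  names(seqs) <- mir_ids
  has_motif <- grepl(spec$motif, seqs, fixed = TRUE)

  labels <- data.frame(
    molecule_id = rep(mol_ids, each = spec$n_mirnas),
    mirna_id = rep(mir_ids, times = spec$n_molecules),
    truth = as.integer(rep(has_n, each = spec$n_mirnas) &
                         rep(has_motif, times = spec$n_molecules)),
    stringsAsFactors = FALSE
  )
  flip <- stats::runif(nrow(labels)) < spec$label_noise
  labels$label <- ifelse(flip, 1L - labels$truth, labels$truth)

  dataset <- association_dataset(
    molecules = smiles, mirnas = seqs,
    positives = labels[labels$label == 1L, c("molecule_id", "mirna_id")]
  )
  list(dataset = dataset, labels = labels, spec = spec)
}

#' Write / read a dataset as the package's on-disk formats
#'
#' `write_dataset` emits `molecules.tsv` (molecule table),
#' `mirnas.fasta` (sequences) and `associations.tsv` (labeled pairs:
#' positives and, when present, sampled negatives) into `dir`;
#' `read_dataset` loads them back into an [association_dataset()]. A
#' write/read/write cycle is byte-identical.
#'
#' @param dataset An [association_dataset()].
#' @param dir Directory (created if missing).
#' @return `write_dataset`: `dir`, invisibly. `read_dataset`: the dataset.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "association_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_molecule_table(dataset$molecules, file.path(dir, "molecules.tsv"))
  write_mirna_fasta(dataset$mirnas, file.path(dir, "mirnas.fasta"))
  write_association_table(labeled_pairs(dataset),
                          file.path(dir, "associations.tsv"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  molecules <- read_molecule_table(file.path(dir, "molecules.tsv"))
  mirnas <- read_mirna_fasta(file.path(dir, "mirnas.fasta"))
  pairs <- read_association_table(file.path(dir, "associations.tsv"))
  association_dataset(
    molecules = molecules, mirnas = mirnas,
    positives = pairs[pairs$label == 1L, , drop = FALSE],
    negatives = pairs[pairs$label == 0L, , drop = FALSE]
  )
}
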