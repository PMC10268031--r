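# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no binary fixtures.

# Pool of SMILES used by property tests: all parse to <= 12 heavy atoms and
# deliberately include rings of different sizes (cyclopropane vs benzene
# vs cyclohexane), which naive iterated-hash fingerprints conflate.
test_smiles_pool <- c(
  "C", "CC", "CCC", "CCO", "CCN", "CO", "CN", "C=CC", "C#N",
  "C1CC1", "C1CCCCC1", "c1ccccc1", "c1ccncc1", "CC(C)O", "CC(=O)O",
  "CC(=O)N", "c1ccccc1O", "c1ccccc1N", "CC1CC1", "OC1CCCCC1",
  "N1CC1", "CC(C)(C)C", "C=CC=C", "CCOC", "CCSC"
)

random_test_molecule <- function() {
  parse_smiles(sample(test_smiles_pool, 1L))
}

# Random relabeling of a molecular graph's atoms; returns the permuted
# graph and the permutation used (new_index = perm[old_index]).
permute_graph <- function(g, perm = sample(nrow(g$atoms))) {
  atoms <- g$atoms[order(perm), , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- g$bonds
  if (nrow(bonds)) {
    bi <- perm[bonds$i]
    bj <- perm[bonds$j]
    bonds <- data.frame(i = pmin(bi, bj), j = pmax(bi, bj),
                        type = bonds$type, stringsAsFactors = FALSE)
    bonds <- bonds[order(bonds$i, bonds$j), , drop = FALSE]
    rownames(bonds) <- NULL
  }
  out <- new_molecular_graph(atoms, bonds)
  out$smiles <- g$smiles
  list(graph = out, perm = perm)
}

# ---- brute-force rooted-neighborhood isomorphism oracle ----------------
# Independent of the package's BLISS-canonicalization route: neighborhoods
# are extracted with igraph::distances and compared pairwise with VF2.

.oracle_neighborhood <- function(g, center, r) {
  ig <- igraph::make_empty_graph(n = nrow(g$atoms), directed = FALSE)
  if (nrow(g$bonds)) {
    ig <- igraph::add_edges(ig, rbind(g$bonds$i, g$bonds$j))
  }
  D <- igraph::distances(ig)
  atom_idx <- which(D[center, ] <= r)
  if (r == 0L || nrow(g$bonds) == 0L) {
    bond_idx <- integer(0)
  } else {
    di <- D[center, g$bonds$i]
    dj <- D[center, g$bonds$j]
    bond_idx <- which(pmax(di, dj) <= r & pmin(di, dj) <= r - 1)
  }
  na <- length(atom_idx)
  acolors <- paste0("a:", g$atoms$symbol[atom_idx], ":",
                    as.integer(g$atoms$aromatic[atom_idx]), ":",
                    as.integer(atom_idx == center))
  bcolors <- if (nb <- length(bond_idx)) {
    paste0("b:", g$bonds$type[bond_idx])
  } else {
    character(0)
  }
  colors <- c(acolors, bcolors)
  sub <- igraph::make_empty_graph(n = na + nb, directed = FALSE)
  if (nb) {
    ai <- match(g$bonds$i[bond_idx], atom_idx)
    aj <- match(g$bonds$j[bond_idx], atom_idx)
    sub <- igraph::add_edges(sub, rbind(c(ai, aj),
                                        rep(na + seq_len(nb), 2L)))
  }
  list(graph = sub, colors = colors)
}

oracle_neighborhoods_isomorphic <- function(nb1, nb2) {
  if (igraph::vcount(nb1$graph) != igraph::vcount(nb2$graph)) return(FALSE)
  if (!identical(sort(nb1$colors), sort(nb2$colors))) return(FALSE)
  all_colors <- sort(unique(c(nb1$colors, nb2$colors)))
  igraph::isomorphic(nb1$graph, nb2$graph, method = "vf2",
                     vertex.color1 = match(nb1$colors, all_colors),
                     vertex.color2 = match(nb2$colors, all_colors))
}

# For a set of graphs, check that fingerprint IDs at radius r agree with
# pairwise rooted-neighborhood isomorphism across ALL vertices of all
# graphs. Returns the fraction of vertex pairs on which the two routes
# agree (1 means exact agreement).
fingerprint_oracle_agreement <- function(graphs, r) {
  vocab <- fingerprint_vocab(r = r)
  fps <- lapply(graphs, fingerprint_graph, r = r, vocab = vocab)
  ids <- unlist(lapply(fps, `[[`, "vertex_fp"), use.names = FALSE)
  nbs <- list()
  k <- 0L
  for (g in graphs) {
    for (v in seq_len(nrow(g$atoms))) {
      k <- k + 1L
      nbs[[k]] <- .oracle_neighborhood(g, v, r)
    }
  }
  n <- length(ids)
  agree <- 0L
  total <- 0L
  for (a in seq_len(n - 1L)) {
    for (b in seq.int(a + 1L, n)) {
      same_id <- ids[a] == ids[b]
      same_iso <- oracle_neighborhoods_isomorphic(nbs[[a]], nbs[[b]])
      total <- total + 1L
      if (same_id == same_iso) agree <- agree + 1L
    }
  }
  agree / total
}

# ---- brute-force AUC oracle --------------------------------------------
# O(P*N) concordant-pair count with half-credit ties.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Small ready-made model fixture for forward-pass tests.
make_toy_model <- function(d = 4L, w = 2L, seed = 7L, smiles = "CCN",
                           sequence = "AUGGCUA", r = 1L, ...) {
  cfg <- molmir_config(d = d, w = w, r = r, ...)
  vocab <- fingerprint_vocab(r = cfg$r)
  mol <- fingerprint_graph(parse_smiles(smiles), r = cfg$r, vocab = vocab)
  freeze_vocab(vocab)
  ts <- tokenize(sequence, n = cfg$n)
  params <- init_model_params(vocab$n_vertex, vocab$n_edge,
                              length(kmer_vocabulary(cfg$n)), cfg,
                              seed = seed)
  list(cfg = cfg, vocab = vocab, mol = mol, ts = ts, params = params)
}
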