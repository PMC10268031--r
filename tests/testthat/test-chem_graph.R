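test_that("SMILES parse to expected heavy-atom graphs", {
  g1 <- parse_smiles("C")
  expect_equal(nrow(g1$atoms), 1L)
  expect_equal(nrow(g1$bonds), 0L)

  g2 <- parse_smiles("CCO")
  expect_equal(nrow(g2$atoms), 3L)
  expect_equal(sort(g2$atoms$symbol), c("C", "C", "O"))
  expect_equal(nrow(g2$bonds), 2L)
  expect_true(all(g2$bonds$type == "single"))
  expect_false(any(g2$atoms$aromatic))

  g3 <- parse_smiles("c1ccccc1")
  expect_equal(nrow(g3$atoms), 6L)
  expect_true(all(g3$atoms$aromatic))
  expect_equal(nrow(g3$bonds), 6L)
  expect_true(all(g3$bonds$type == "aromatic"))
})

test_that("unparseable or empty SMILES raise errors naming the input", {
  expect_error(parse_smiles("xx((bad"), "xx\\(\\(bad")
  expect_error(parse_smiles(""), "non-empty")
  expect_error(parse_smiles("   "), "non-empty")
})

test_that("adjacency is symmetric, self-loop free, consistent with bonds", {
  for (smi in c("CCO", "c1ccncc1", "CC(C)O", "C1CC1", "CC(=O)O")) {
    g <- parse_smiles(smi)
    nv <- nrow(g$atoms)
    for (v in seq_len(nv)) {
      expect_false(v %in% g$adjacency[[v]])
      for (u in g$adjacency[[v]]) expect_true(v %in% g$adjacency[[u]])
    }
    for (k in seq_len(nrow(g$bonds))) {
      expect_true(g$bonds$j[k] %in% g$adjacency[[g$bonds$i[k]]])
      expect_true(g$bonds$i[k] %in% g$adjacency[[g$bonds$j[k]]])
    }
  }
})

test_that("radius-0 fingerprints reduce to atom labels", {
  v <- fingerprint_vocab(r = 0)
  g <- fingerprint_graph(parse_smiles("CCO"), r = 0, vocab = v)
  # two carbons share an ID, oxygen differs
  expect_equal(g$vertex_fp[1], g$vertex_fp[2])
  expect_equal(length(unique(g$vertex_fp)), 2L)
  gb <- fingerprint_graph(parse_smiles("c1ccccc1"), r = 0, vocab = v)
  expect_equal(length(unique(gb$vertex_fp)), 1L)
  # aromatic carbon is a different label than aliphatic carbon
  expect_false(gb$vertex_fp[1] %in% g$vertex_fp)
})

test_that("radius-1 fingerprints distinguish chemically distinct atoms", {
  v <- fingerprint_vocab(r = 1)
  gb <- fingerprint_graph(parse_smiles("c1ccccc1"), r = 1, vocab = v)
  expect_equal(length(unique(gb$vertex_fp)), 1L)  # all benzene C equivalent
  expect_equal(length(unique(gb$edge_fp)), 1L)
  ge <- fingerprint_graph(parse_smiles("CCO"), r = 1, vocab = v)
  expect_equal(length(unique(ge$vertex_fp)), 3L)  # CH3, CH2, OH all differ
  expect_equal(length(ge$vertex_fp), 3L)
  expect_equal(length(ge$edge_fp), 2L)
})

test_that("fingerprint IDs are invariant to atom relabeling", {
  set.seed(41)
  for (smi in c("CCO", "c1ccncc1", "CC(C)O", "OC1CCCCC1")) {
    g <- parse_smiles(smi)
    for (r in 0:2) {
      vocab <- fingerprint_vocab(r = r)
      ref <- fingerprint_graph(g, r = r, vocab = vocab)
      for (rep in 1:3) {
        pg <- permute_graph(g)$graph
        pfp <- fingerprint_graph(pg, r = r, vocab = vocab)
        expect_equal(sort(pfp$vertex_fp), sort(ref$vertex_fp))
        expect_equal(sort(pfp$edge_fp), sort(ref$edge_fp))
      }
    }
  }
})

test_that("same ID iff rooted neighborhoods are isomorphic (brute force)", {
  set.seed(11)
  graphs <- lapply(sample(test_smiles_pool, 12L), parse_smiles)
  for (r in 0:2) {
    expect_equal(fingerprint_oracle_agreement(graphs, r), 1)
  }
})

test_that("radius-(r+1) partitions refine radius-r partitions", {
  for (smi in c("CCO", "c1ccncc1", "CC(C)O", "C1CC1", "CCCCN")) {
    g <- parse_smiles(smi)
    ids <- lapply(0:3, function(r) {
      fingerprint_graph(g, r = r, vocab = fingerprint_vocab(r))$vertex_fp
    })
    for (k in 1:3) {
      # vertices sharing a radius-(k) ID must share the radius-(k-1) ID
      finer <- ids[[k + 1L]]
      coarser <- ids[[k]]
      for (a in seq_along(finer)) {
        same <- which(finer == finer[a])
        expect_true(all(coarser[same] == coarser[a]))
      }
    }
  }
})

test_that("frozen vocabularies map unseen signatures to the unknown ID", {
  vocab <- fingerprint_vocab(r = 1)
  fingerprint_graph(parse_smiles("CCO"), r = 1, vocab = vocab)
  n_before <- vocab$n_vertex
  freeze_vocab(vocab)
  g <- fingerprint_graph(parse_smiles("c1ccncc1"), r = 1, vocab = vocab)
  expect_true(all(g$vertex_fp == 0L))
  expect_equal(vocab$n_vertex, n_before)  # table did not grow
  # known chemistry still resolves to its old IDs
  g2 <- fingerprint_graph(parse_smiles("CCO"), r = 1, vocab = vocab)
  expect_true(all(g2$vertex_fp > 0L))
})

test_that("vocabulary JSON persistence preserves IDs and rejects bad radii", {
  vocab <- fingerprint_vocab(r = 2)
  g <- fingerprint_graph(parse_smiles("CC(=O)O"), r = 2, vocab = vocab)
  path <- withr::local_tempfile(fileext = ".json")
  write_fingerprint_vocab(vocab, path)
  back <- read_fingerprint_vocab(path)
  g2 <- fingerprint_graph(parse_smiles("CC(=O)O"), r = 2, vocab = back)
  expect_identical(g2$vertex_fp, g$vertex_fp)
  expect_identical(g2$edge_fp, g$edge_fp)
  expect_false(back$frozen)
  freeze_vocab(vocab)
  write_fingerprint_vocab(vocab, path)
  expect_true(read_fingerprint_vocab(path)$frozen)
  expect_error(read_fingerprint_vocab(path, expected_r = 1), "mismatch")
  expect_error(fingerprint_graph(parse_smiles("C"), r = 1, vocab = back),
               "r = 2")
})

test_that("negative radius is rejected", {
  v <- fingerprint_vocab(r = 2)
  expect_error(fingerprint_graph(parse_smiles("C"), r = -1, vocab = v),
               "non-negative")
})
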