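# Hand-built two-atom fixture: one single bond, d = 2.
two_atom_fixture <- function(seed = 3L) {
  fx <- make_toy_model(d = 2L, w = 1L, seed = seed, smiles = "CO",
                       sequence = "AUG", r = 0L)
  fx
}

test_that("a vertex with no neighbors is squashed through the sigmoid", {
  fx <- make_toy_model(d = 2L, w = 1L, smiles = "C", sequence = "AUG",
                       r = 0L)
  v0 <- matrix(0, 1, 2)
  e0 <- matrix(0, 0, 2)
  out <- vertex_update(fx$mol, v0, e0, fx$params)
  expect_equal(out, matrix(0.5, 1, 2))  # sigmoid(0) with an empty sum
})

test_that("all-negative messages are killed by the ReLU", {
  fx <- two_atom_fixture()
  p <- fx$params
  p$W_neighbor[] <- 0
  p$b_neighbor[] <- -1
  v0 <- matrix(c(0.3, -0.2, 0.1, 0.4), 2, 2)
  e0 <- matrix(c(0.5, 0.6), 1, 2)
  out <- vertex_update(fx$mol, v0, e0, p)
  expect_equal(out, 1 / (1 + exp(-v0)))
})

test_that("vertex update matches a scalar hand evaluation", {
  fx <- two_atom_fixture()
  p <- fx$params
  v0 <- matrix(c(0.1, 0.2, -0.3, 0.4), 2, 2)
  e0 <- matrix(c(0.5, -0.1), 1, 2)
  out <- vertex_update(fx$mol, v0, e0, p)
  # vertex 1's only neighbor is vertex 2 through the single edge
  for (i in 1:2) {
    j <- 3L - i
    msg <- pmax(0, as.numeric(p$W_neighbor %*% c(v0[j, ], e0[1, ])) +
                  p$b_neighbor)
    expect_equal(out[i, ], 1 / (1 + exp(-(v0[i, ] + msg))), tolerance = 1e-12)
  }
})

test_that("edge update reduces to sigmoid pass-through when g vanishes", {
  fx <- two_atom_fixture()
  p <- fx$params
  p$b_side[] <- 0
  v0 <- matrix(c(0.4, -0.4, -0.2, 0.2), 2, 2)  # v1 = -v2 componentwise
  e0 <- matrix(c(0.3, 0.8), 1, 2)
  out <- edge_update(fx$mol, v0, e0, p)
  expect_equal(out, 1 / (1 + exp(-e0)))
  p2 <- fx$params
  p2$W_side[] <- 0
  p2$b_side[] <- 0
  out2 <- edge_update(fx$mol, matrix(rnorm(4), 2, 2), e0, p2)
  expect_equal(out2, 1 / (1 + exp(-e0)))
})

test_that("edge update matches a scalar hand evaluation", {
  fx <- two_atom_fixture()
  p <- fx$params
  v <- matrix(c(0.2, 0.7, -0.1, 0.5), 2, 2)
  e0 <- matrix(c(-0.3, 0.6), 1, 2)
  gvec <- pmax(0, as.numeric(p$W_side %*% (v[1, ] + v[2, ])) + p$b_side)
  expect_equal(edge_update(fx$mol, v, e0, p)[1, ],
               1 / (1 + exp(-(e0[1, ] + gvec))), tolerance = 1e-12)
})

test_that("all updated states stay strictly inside (0, 1)", {
  fx <- make_toy_model(d = 8L, smiles = "c1ccncc1", sequence = "AUGGCAUGG",
                       r = 1L)
  v <- matrix(rnorm(6 * 8, sd = 3), 6, 8)
  e <- matrix(rnorm(6 * 8, sd = 3), 6, 8)
  vu <- vertex_update(fx$mol, v, e, fx$params)
  eu <- edge_update(fx$mol, v, e, fx$params)
  expect_true(all(vu > 0 & vu < 1))
  expect_true(all(eu > 0 & eu < 1))
})

test_that("shape mismatches are hard errors", {
  fx <- two_atom_fixture()
  expect_error(vertex_update(fx$mol, matrix(0, 3, 2), matrix(0, 1, 2),
                             fx$params), "matrix")
  expect_error(edge_update(fx$mol, matrix(0, 2, 3), matrix(0, 1, 2),
                           fx$params), "matrix")
})

test_that("encoding an empty or unfingerprinted graph fails", {
  fx <- two_atom_fixture()
  raw <- parse_smiles("CC")
  expect_error(encode_molecule(raw, fx$params), "fingerprint")
})

test_that("encode_molecule is invariant to atom relabeling", {
  set.seed(5)
  for (smi in c("CC(C)O", "c1ccncc1", "OC1CCCCC1")) {
    g <- parse_smiles(smi)
    vocab <- fingerprint_vocab(r = 2)
    ref <- fingerprint_graph(g, r = 2, vocab = vocab)
    cfg <- molmir_config(d = 8)
    params <- init_model_params(vocab$n_vertex, vocab$n_edge, 64, cfg,
                                seed = 2)
    y_ref <- encode_molecule(ref, params, T = 2)
    for (rep in 1:5) {
      pg <- fingerprint_graph(permute_graph(g)$graph, r = 2, vocab = vocab)
      expect_equal(encode_molecule(pg, params, T = 2), y_ref,
                   tolerance = 1e-6)
    }
  }
})

test_that("readout is the arithmetic mean of final vertex states", {
  # T = 0 skips all updates, so the readout averages the raw embeddings
  fx <- two_atom_fixture()
  y <- encode_molecule(fx$mol, fx$params, T = 0)
  rows <- fx$mol$vertex_fp + 1L
  expect_equal(y, colMeans(fx$params$vertex_embedding[rows, , drop = FALSE]))
})
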