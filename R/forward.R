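# Forward-pass primitives. All states are kept as row-per-entity matrices
# (|V| x d vertex states, |E| x d edge states, windows x d sequence states)
# so each update is a couple of small matrix products.

sigmoid <- function(x) stats::plogis(x)
relu <- function(x) {
  x[x < 0] <- 0
  x
}

# add a bias vector to every row of a matrix (column-major recycling)
.addb <- function(X, b) X + rep(b, each = nrow(X))

.check_state <- function(m, nr, d, what) {
  if (!is.matrix(m) || nrow(m) != nr || ncol(m) != d) {
    stop(what, " must be a ", nr, " x ", d, " matrix", call. = FALSE)
  }
}

#' One round of vertex state updates in the molecule encoder
#'
#' Each vertex receives a message from every neighbor, computed from the
#' neighbor's state and the state of the connecting bond:
#' `h_ij = relu(W_neighbor [v_j; e_ij] + b_neighbor)`, and integrates them
#' through a squashing update `v_i <- sigmoid(v_i + sum_j h_ij)`. A vertex
#' with no neighbors keeps an empty sum, so its state passes through the
#' sigmoid unchanged by messages.
#'
#' @param g Fingerprinted `molecular_graph`.
#' @param vstate `|V| x d` matrix of current vertex states.
#' @param estate `|E| x d` matrix of current edge states.
#' @param params [init_model_params()] list.
#' @return Updated `|V| x d` matrix with entries strictly in (0, 1).
#' @export
vertex_update <- function(g, vstate, estate, params) {
  d <- ncol(params$W_neighbor) / 2L
  nv <- nrow(g$atoms)
  ne <- nrow(g$bonds)
  .check_state(vstate, nv, d, "vstate")
  if (ne > 0L) .check_state(estate, ne, d, "estate")
  if (ne == 0L) return(sigmoid(vstate))
  A <- cbind(vstate[g$dsrc, , drop = FALSE],
             estate[g$deid, , drop = FALSE])
  H <- relu(.addb(A %*% t(params$W_neighbor), params$b_neighbor))
  sigmoid(vstate + g$Gdst %*% H)
}

#' One round of edge state updates in the molecule encoder
#'
#' Each bond pools its two endpoint vertex states symmetrically:
#' `g_ij = relu(W_side (v_i + v_j) + b_side)`, then
#' `e_ij <- sigmoid(e_ij + g_ij)`.
#'
#' @inheritParams vertex_update
#' @return Updated `|E| x d` matrix with entries strictly in (0, 1).
#' @export
edge_update <- function(g, vstate, estate, params) {
  d <- ncol(params$W_side)
  nv <- nrow(g$atoms)
  ne <- nrow(g$bonds)
  .check_state(vstate, nv, d, "vstate")
  if (ne == 0L) return(estate)
  .check_state(estate, ne, d, "estate")
  G <- relu(.addb((g$Gend %*% vstate) %*% t(params$W_side), params$b_side))
  sigmoid(estate + G)
}

# Full molecule encoder with optional cache for backprop.
.encode_molecule <- function(g, params, T, keep = FALSE) {
  nv <- nrow(g$atoms)
  if (nv == 0L) stop("cannot encode an empty molecular graph", call. = FALSE)
  if (is.null(g$vertex_fp)) {
    stop("graph must be fingerprinted before encoding", call. = FALSE)
  }
  d <- ncol(params$vertex_embedding)
  vrow <- g$vertex_fp + 1L
  erow <- g$edge_fp + 1L
  V <- params$vertex_embedding[vrow, , drop = FALSE]
  E <- params$edge_embedding[erow, , drop = FALSE]
  cache <- if (keep) {
    list(vrow = vrow, erow = erow, V = vector("list", T + 1L),
         E = vector("list", T + 1L), H = vector("list", T),
         G = vector("list", T))
  }
  if (keep) {
    cache$V[[1L]] <- V
    cache$E[[1L]] <- E
  }
  ne <- nrow(g$bonds)
  tWn <- t(params$W_neighbor)
  tWs <- t(params$W_side)
  for (t in seq_len(T)) {
    if (ne > 0L) {
      A <- cbind(V[g$dsrc, , drop = FALSE], E[g$deid, , drop = FALSE])
      H <- relu(.addb(A %*% tWn, params$b_neighbor))
      Vnew <- sigmoid(V + g$Gdst %*% H)
      G <- relu(.addb((g$Gend %*% Vnew) %*% tWs, params$b_side))
      Enew <- sigmoid(E + G)
    } else {
      H <- NULL
      Vnew <- sigmoid(V)
      G <- NULL
      Enew <- E
    }
    if (keep) {
      cache$H[[t]] <- H
      cache$G[[t]] <- G
      cache$V[[t + 1L]] <- Vnew
      cache$E[[t + 1L]] <- Enew
    }
    V <- Vnew
    E <- Enew
  }
  y <- colMeans(V)
  if (keep) list(y_sm = y, cache = cache) else y
}

#' Encode a molecule into a d-vector
#'
#' Looks up the fingerprint embeddings as initial vertex/edge states, runs
#' `T` alternating rounds of [vertex_update()] and [edge_update()] (vertex
#' first, each edge round using the fresh vertex states), and returns the
#' mean of the final vertex states.
#'
#' @param g Fingerprinted `molecular_graph`.
#' @param params [init_model_params()] list.
#' @param T Number of update rounds (default 2).
#' @return Numeric vector of length `d`.
#' @export
encode_molecule <- function(g, params, T = 2L) {
  .encode_molecule(g, params, as.integer(T), keep = FALSE)
}

#' Embed the n-mer windows of a token sequence
#'
#' Each token ID is looked up in the word embedding table (unknown ID 0
#' uses the reserved first row), and `w` consecutive word vectors are
#' concatenated per position, giving `n_tokens - w + 1` window vectors of
#' length `d * w`.
#'
#' @param ts A [tokenize()]d sequence.
#' @param params [init_model_params()] list.
#' @param w Window size in words (default: the width the parameters were
#'   built with).
#' @return `(n_tokens - w + 1) x (d w)` matrix of window vectors.
#' @export
embed_windows <- function(ts, params, w = attr(params, "w")) {
  stopifnot(inherits(ts, "token_sequence"))
  w <- as.integer(w)
  ntok <- length(ts$tokens)
  if (ntok < w) {
    stop("sequence has ", ntok, " tokens, fewer than the window size ", w,
         call. = FALSE)
  }
  X <- params$word_embedding[ts$tokens + 1L, , drop = FALSE]
  nwin <- ntok - w + 1L
  do.call(cbind, lapply(seq_len(w) - 1L, function(k) {
    X[seq_len(nwin) + k, , drop = FALSE]
  }))
}

# Conv stack with cache: layer 1 maps dw -> d, layers 2..L map d -> d,
# position-wise (no cross-position mixing beyond the window concatenation).
.filter_stack <- function(C0, params, keep = FALSE) {
  L <- attr(params, "L")
  cn <- .conv_names(L)
  layers <- if (keep) vector("list", L)
  C <- C0
  for (l in seq_len(L)) {
    C <- relu(.addb(C %*% t(params[[cn$W[l]]]), params[[cn$b[l]]]))
    if (keep) layers[[l]] <- C
  }
  if (keep) list(C = C, layers = layers) else C
}

#' Apply the convolutional filter stack to embedded windows
#'
#' Layer 1 maps each `d w` window vector to a `d`-dimensional hidden
#' vector through an affine map and ReLU; subsequent layers apply further
#' `d x d` affine+ReLU maps per position.
#'
#' @param c0 Matrix of window vectors from [embed_windows()].
#' @param params [init_model_params()] list.
#' @return `n_windows x d` matrix of hidden vectors (the set `C`).
#' @export
filter_stack <- function(c0, params) {
  .filter_stack(c0, params, keep = FALSE)
}

#' Plain mean readout over sequence hidden vectors
#'
#' The pre-attention sequence summary: the unweighted average of the
#' hidden vectors. The full model replaces this with the
#' attention-weighted readout unless attention is switched off.
#'
#' @param C `n_windows x d` matrix of hidden vectors.
#' @return Numeric vector of length `d`.
#' @export
sequence_readout <- function(C) {
  if (!is.matrix(C) || nrow(C) == 0L) {
    stop("hidden vector set is empty", call. = FALSE)
  }
  colMeans(C)
}

#' Attention weights of sequence windows against a molecule
#'
#' Both the molecule embedding and each sequence hidden vector are mapped
#' through a shared affine+ReLU transform; the attention weight of window
#' `i` is the sigmoid of the dot product `h_sm . h_i`. Weights are
#' intentionally not normalized across windows (sigmoid, not softmax), so
#' each lies in (0, 1) independently and measures the strength of the
#' molecule/window interaction.
#'
#' @param y_sm Molecule embedding (length `d`).
#' @param C `n_windows x d` hidden vectors from [filter_stack()].
#' @param params [init_model_params()] list.
#' @return List with `alpha` (length `n_windows`, each in (0,1)), `h`
#'   (`n_windows x d` transformed hidden vectors) and `h_sm` (length `d`).
#' @export
attention_weights <- function(y_sm, C, params) {
  if (!is.matrix(C) || nrow(C) == 0L) {
    stop("hidden vector set is empty", call. = FALSE)
  }
  h_sm <- as.numeric(relu(params$W_inter %*% y_sm + params$b_inter))
  h <- relu(.addb(C %*% t(params$W_inter), params$b_inter))
  alpha <- as.numeric(sigmoid(h %*% h_sm))
  list(alpha = alpha, h = h, h_sm = h_sm)
}

#' Attention-weighted sequence readout
#'
#' The weighted sum `sum_i alpha_i h_i` over the transformed hidden
#' vectors, replacing the plain mean of [sequence_readout()] in the full
#' model.
#'
#' @param alpha Attention weights (length `n_windows`).
#' @param h `n_windows x d` transformed hidden vectors (from
#'   [attention_weights()]).
#' @return Numeric vector of length `d`.
#' @export
attended_readout <- function(alpha, h) {
  if (!is.matrix(h) || length(alpha) != nrow(h)) {
    stop("attention weights and hidden vectors do not align", call. = FALSE)
  }
  as.numeric(crossprod(h, alpha))
}

#' Classify a molecule-miRNA pair from the two embeddings
#'
#' Concatenates the sequence and molecule embeddings, applies the output
#' projection to two logits, and returns softmax probabilities
#' `(P_0, P_1)`; `P_1` is the association probability.
#'
#' @param y_mirna Sequence embedding (length `d`).
#' @param y_sm Molecule embedding (length `d`).
#' @param params [init_model_params()] list.
#' @return Numeric vector `c(P_0, P_1)` summing to 1.
#' @export
classify <- function(y_mirna, y_sm, params) {
  z <- as.numeric(params$W_output %*% c(y_mirna, y_sm) + params$b_output)
  if (any(!is.finite(z))) {
    stop("non-finite classification logits", call. = FALSE)
  }
  softmax2(z)
}

softmax2 <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# Full forward pass for one (molecule, sequence) pair, with all
# intermediates cached when gradients are needed.
forward_pair <- function(mol, ts, params, config, keep = FALSE) {
  enc <- .encode_molecule(mol, params, config$T, keep = keep)
  y_sm <- if (keep) enc$y_sm else enc
  C0 <- embed_windows(ts, params, config$w)
  fs <- .filter_stack(C0, params, keep = keep)
  C <- if (keep) fs$C else fs
  if (config$attention) {
    att <- attention_weights(y_sm, C, params)
    y_mi <- attended_readout(att$alpha, att$h)
    alpha <- att$alpha
  } else {
    att <- NULL
    y_mi <- sequence_readout(C)
    alpha <- NULL
  }
  z <- as.numeric(params$W_output %*% c(y_mi, y_sm) + params$b_output)
  if (any(!is.finite(z))) {
    stop("non-finite classification logits", call. = FALSE)
  }
  p <- softmax2(z)
  out <- list(prob = p, alpha = alpha)
  if (keep) {
    out$cache <- list(mol = mol, ts = ts, enc = enc$cache, y_sm = y_sm,
                      C0 = C0, layers = fs$layers, C = C, att = att,
                      y_mi = y_mi, z = z, p = p)
  }
  out
}
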