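#' Parse a SMILES string into a molecular graph
#'
#' Converts a SMILES string into a heavy-atom molecular graph with aromatic
#' perception, using OpenBabel (via \pkg{ChemmineOB}) as the chemistry
#' backend. Atom ordering follows the parser's canonical output order and is
#' deterministic for a given input string.
#'
#' @param smiles A single non-empty SMILES string.
#' @param strip_hydrogens Drop explicit hydrogens so only heavy atoms remain
#'   (default `TRUE`). Implicit hydrogens are never materialized.
#' @param molecule_id Optional identifier stored on the graph.
#'
#' @return An object of class `molecular_graph`: a list with
#'   \describe{
#'     \item{atoms}{data.frame with `symbol` (element) and `aromatic` (logical).}
#'     \item{bonds}{data.frame with 1-based endpoint indices `i < j` and
#'       `type` in `single`, `double`, `triple`, `aromatic`.}
#'     \item{adjacency}{list of integer vectors, the neighbor indices of each
#'       atom.}
#'     \item{vertex_fp, edge_fp}{fingerprint IDs, `NULL` until
#'       [fingerprint_graph()] is applied.}
#'   }
#' @examples
#' g <- parse_smiles("CCO")
#' nrow(g$atoms)  # 3 heavy atoms
#' @export
parse_smiles <- function(smiles, strip_hydrogens = TRUE, molecule_id = NULL) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    stop("`smiles` must be a single non-empty string", call. = FALSE)
  }
  smiles <- trimws(smiles)
  opts <- if (isTRUE(strip_hydrogens)) {
    data.frame(names = "d", args = "", stringsAsFactors = FALSE)
  } else {
    NULL
  }
  mol2 <- ChemmineOB::convertFormat("SMI", "MOL2", paste0(smiles, "\n"),
                                    options = opts)
  g <- .parse_mol2_block(mol2)
  if (is.null(g) || nrow(g$atoms) == 0L) {
    stop("cannot parse SMILES string: '", smiles, "'", call. = FALSE)
  }
  g$smiles <- smiles
  g$molecule_id <- molecule_id
  g
}

# Minimal reader for the @<TRIPOS>ATOM / @<TRIPOS>BOND blocks of a single
# MOL2 record. SYBYL atom types carry aromaticity as the ".ar" suffix.
.parse_mol2_block <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  a0 <- which(lines == "@<TRIPOS>ATOM")
  if (length(a0) == 0L) return(NULL)
  a0 <- a0[1L]
  b0 <- which(lines == "@<TRIPOS>BOND")
  b0 <- if (length(b0)) b0[1L] else length(lines) + 1L
  marks <- grep("^@<TRIPOS>", lines)

  atom_lines <- lines[seq.int(a0 + 1L, b0 - 1L)]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  if (length(atom_lines) == 0L) return(NULL)
  afields <- strsplit(trimws(atom_lines), "[[:space:]]+")
  sybyl <- vapply(afields, `[[`, "", 6L)
  symbol <- sub("\\..*$", "", sybyl)
  aromatic <- grepl("\\.ar$", sybyl)

  bond_end <- marks[marks > b0]
  bond_end <- if (length(bond_end)) bond_end[1L] - 1L else length(lines)
  bonds <- data.frame(i = integer(0), j = integer(0), type = character(0),
                      stringsAsFactors = FALSE)
  if (b0 <= length(lines) && bond_end > b0) {
    bond_lines <- lines[seq.int(b0 + 1L, bond_end)]
    bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
    if (length(bond_lines)) {
      bfields <- strsplit(trimws(bond_lines), "[[:space:]]+")
      bi <- as.integer(vapply(bfields, `[[`, "", 2L))
      bj <- as.integer(vapply(bfields, `[[`, "", 3L))
      braw <- vapply(bfields, `[[`, "", 4L)
      type <- c(`1` = "single", `2` = "double", `3` = "triple",
                ar = "aromatic", am = "single")[braw]
      if (anyNA(type)) {
        stop("unsupported bond type in parsed molecule: ",
             paste(unique(braw[is.na(type)]), collapse = ", "), call. = FALSE)
      }
      bonds <- data.frame(i = pmin(bi, bj), j = pmax(bi, bj),
                          type = unname(type), stringsAsFactors = FALSE)
    }
  }
  new_molecular_graph(data.frame(symbol = symbol, aromatic = aromatic,
                                 stringsAsFactors = FALSE), bonds)
}

#' Construct a molecular graph from atom and bond tables
#'
#' Low-level constructor used by [parse_smiles()] and by tests that need
#' hand-built graphs. Validates symmetry and index ranges and builds the
#' adjacency structure.
#'
#' @param atoms data.frame with columns `symbol` and `aromatic`.
#' @param bonds data.frame with columns `i`, `j` (1-based, `i < j`) and
#'   `type`.
#' @return A `molecular_graph` object.
#' @export
new_molecular_graph <- function(atoms, bonds) {
  nv <- nrow(atoms)
  if (nrow(bonds)) {
    stopifnot(all(bonds$i >= 1L), all(bonds$j <= nv), all(bonds$i < bonds$j))
  }
  adj <- vector("list", nv)
  for (v in seq_len(nv)) adj[[v]] <- integer(0)
  ne <- nrow(bonds)
  for (k in seq_len(ne)) {
    adj[[bonds$i[k]]] <- c(adj[[bonds$i[k]]], bonds$j[k])
    adj[[bonds$j[k]]] <- c(adj[[bonds$j[k]]], bonds$i[k])
  }
  # directed-edge arrays used by the message-passing encoder: one message
  # per bond per direction, src -> dst carrying the bond's edge state
  if (ne) {
    dsrc <- c(bonds$i, bonds$j)
    ddst <- c(bonds$j, bonds$i)
    deid <- c(seq_len(ne), seq_len(ne))
    # static gather/scatter indicators so state updates are plain matrix
    # products: Gdst sums directed-edge messages into their target vertex,
    # Gsrc/Geid scatter gradients back, Gend sums a bond's endpoint states
    Gdst <- matrix(0, nv, 2L * ne)
    Gdst[cbind(ddst, seq_len(2L * ne))] <- 1
    Gsrc <- matrix(0, nv, 2L * ne)
    Gsrc[cbind(dsrc, seq_len(2L * ne))] <- 1
    Geid <- matrix(0, ne, 2L * ne)
    Geid[cbind(deid, seq_len(2L * ne))] <- 1
    Gend <- matrix(0, ne, nv)
    Gend[cbind(seq_len(ne), bonds$i)] <- 1
    Gend[cbind(seq_len(ne), bonds$j)] <- 1
  } else {
    dsrc <- ddst <- deid <- integer(0)
    Gdst <- Gsrc <- Geid <- Gend <- NULL
  }
  structure(list(atoms = atoms, bonds = bonds, adjacency = adj,
                 dsrc = dsrc, ddst = ddst, deid = deid,
                 Gdst = Gdst, Gsrc = Gsrc, Geid = Geid, Gend = Gend,
                 vertex_fp = NULL, edge_fp = NULL),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph>", nrow(x$atoms), "atoms,", nrow(x$bonds), "bonds")
  if (!is.null(x$smiles)) cat(" [", x$smiles, "]", sep = "")
  if (!is.null(x$vertex_fp)) {
    cat("  fingerprinted (r =", attr(x, "fingerprint_r"), ")")
  }
  cat("\n")
  invisible(x)
}

# All-pairs shortest path (hop) distances by BFS over the adjacency list.
.graph_distances <- function(g) {
  nv <- nrow(g$atoms)
  D <- matrix(Inf, nv, nv)
  for (s in seq_len(nv)) {
    dist <- rep(Inf, nv)
    dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- unique(unlist(g$adjacency[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(dist[nxt])]
      dist[nxt] <- dist[frontier[1L]] + 1
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

# Canonical signature of a rooted labeled subgraph. Bond types are encoded
# by subdividing each bond with a colored pseudo-vertex, so BLISS canonical
# labeling of the vertex-colored graph canonicalizes the edge-labeled graph.
# Two subgraphs get equal signature strings iff they are isomorphic as
# rooted, atom- and bond-labeled graphs.
.canonical_signature <- function(g, atom_idx, bond_idx, roots) {
  na <- length(atom_idx)
  nb <- length(bond_idx)
  colors <- c(
    sprintf("a:%s:%d:%d", g$atoms$symbol[atom_idx],
            as.integer(g$atoms$aromatic[atom_idx]),
            as.integer(atom_idx %in% roots)),
    sprintf("b:%s", g$bonds$type[bond_idx])
  )
  if (nb == 0L) {
    # no bonds: the multiset of atom colors is already canonical
    return(paste0("V[", paste(sort(colors), collapse = ","), "]E[]"))
  }
  ai <- match(g$bonds$i[bond_idx], atom_idx)
  aj <- match(g$bonds$j[bond_idx], atom_idx)
  el <- rbind(cbind(ai, na + seq_len(nb)), cbind(aj, na + seq_len(nb)))
  ig <- igraph::make_empty_graph(n = na + nb, directed = FALSE)
  ig <- igraph::add_edges(ig, t(el))
  code <- match(colors, sort(unique(colors)))
  perm <- igraph::canonical_permutation(ig, colors = code)$labeling
  canon_colors <- character(length(colors))
  canon_colors[perm] <- colors
  ce <- cbind(perm[el[, 1L]], perm[el[, 2L]])
  ce <- cbind(pmin(ce[, 1L], ce[, 2L]), pmax(ce[, 1L], ce[, 2L]))
  ce <- ce[order(ce[, 1L], ce[, 2L]), , drop = FALSE]
  paste0("V[", paste(canon_colors, collapse = ","), "]E[",
         paste(ce[, 1L], ce[, 2L], sep = "-", collapse = ","), "]")
}

# Extraction rules for the radius-r neighborhood around a vertex or an edge.
# Vertex: atoms within hop distance r of the center; bonds whose endpoints
# lie at distance <= r and <= r-1 (so at r = 0 the subgraph is the bare
# atom). Edge: atoms within r-1 of either endpoint, bonds included around
# both endpoints (intersection rule), plus any endpoint atoms those bonds
# require; at r = 0 the subgraph is the bond with its two atoms.
.vertex_signature <- function(g, center, r, D) {
  atom_idx <- which(D[center, ] <= r)
  if (r == 0L || nrow(g$bonds) == 0L) {
    bond_idx <- integer(0)
  } else {
    di <- D[center, g$bonds$i]
    dj <- D[center, g$bonds$j]
    bond_idx <- which(pmax(di, dj) <= r & pmin(di, dj) <= r - 1)
  }
  .canonical_signature(g, atom_idx, bond_idx, roots = center)
}

.edge_signature <- function(g, k, r, D) {
  i <- g$bonds$i[k]
  j <- g$bonds$j[k]
  if (r == 0L) {
    return(.canonical_signature(g, c(i, j), k, roots = c(i, j)))
  }
  atom_idx <- which(D[i, ] <= r - 1 | D[j, ] <= r - 1)
  di_i <- D[i, g$bonds$i]; di_j <- D[i, g$bonds$j]
  dj_i <- D[j, g$bonds$i]; dj_j <- D[j, g$bonds$j]
  in_i <- pmax(di_i, di_j) <= r & pmin(di_i, di_j) <= r - 1
  in_j <- pmax(dj_i, dj_j) <= r & pmin(dj_i, dj_j) <= r - 1
  bond_idx <- which(in_i & in_j)
  atom_idx <- sort(unique(c(atom_idx, g$bonds$i[bond_idx],
                            g$bonds$j[bond_idx])))
  .canonical_signature(g, atom_idx, bond_idx, roots = c(i, j))
}

#' Assign r-radius fingerprint IDs to the atoms and bonds of a graph
#'
#' Each atom receives an integer ID encoding the canonical form of its
#' radius-`r` neighborhood subgraph (atoms, bonds, aromaticity, rooted at
#' the atom); each bond receives an ID for the neighborhood rooted at its
#' two endpoints. Two atoms share an ID exactly when their rooted
#' neighborhoods are isomorphic as labeled graphs. IDs index the embedding
#' tables of the molecule encoder.
#'
#' A growing (unfrozen) vocabulary assigns fresh dense IDs to new
#' signatures; a frozen vocabulary maps unseen signatures to the reserved
#' unknown ID 0, which is how molecules absent from training are handled.
#'
#' @param g A `molecular_graph` from [parse_smiles()].
#' @param r Non-negative integer neighborhood radius. At `r = 0` the vertex
#'   signature is the atom label alone.
#' @param vocab A [fingerprint_vocab()] created with the same `r`.
#' @return `g` with `vertex_fp` and `edge_fp` integer vectors populated.
#' @examples
#' v <- fingerprint_vocab(r = 1)
#' g <- fingerprint_graph(parse_smiles("c1ccccc1"), r = 1, vocab = v)
#' unique(g$vertex_fp)  # one ID: all benzene carbons are equivalent
#' @export
fingerprint_graph <- function(g, r = 2L, vocab) {
  stopifnot(inherits(g, "molecular_graph"), inherits(vocab, "fingerprint_vocab"))
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0) {
    stop("`r` must be a non-negative integer", call. = FALSE)
  }
  r <- as.integer(r)
  if (vocab$r != r) {
    stop("vocabulary was built for r = ", vocab$r,
         ", cannot fingerprint at r = ", r, call. = FALSE)
  }
  D <- .graph_distances(g)
  nv <- nrow(g$atoms)
  ne <- nrow(g$bonds)
  vsig <- vapply(seq_len(nv), function(v) .vertex_signature(g, v, r, D), "")
  esig <- vapply(seq_len(ne), function(k) .edge_signature(g, k, r, D), "")
  g$vertex_fp <- vocab_ids(vocab, vsig, table = "vertex")
  g$edge_fp <- vocab_ids(vocab, esig, table = "edge")
  attr(g, "fingerprint_r") <- r
  g
}
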