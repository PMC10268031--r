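#' Create an empty fingerprint vocabulary
#'
#' A fingerprint vocabulary maps canonical neighborhood signatures to dense
#' non-negative integer IDs, with separate tables for vertex (atom-rooted)
#' and edge (bond-rooted) signatures. ID 0 is reserved for signatures not
#' present in the vocabulary (the "unknown" fingerprint, used after
#' freezing); assigned IDs start at 1 and grow densely in first-seen order.
#'
#' The object has reference semantics (it is an environment): growing it
#' inside [fingerprint_graph()] updates the vocabulary in place.
#'
#' @param r The neighborhood radius the vocabulary is tied to; graphs may
#'   only be fingerprinted against a vocabulary built with the same radius.
#' @return An object of class `fingerprint_vocab`.
#' @seealso [freeze_vocab()], [write_fingerprint_vocab()]
#' @export
fingerprint_vocab <- function(r = 2L) {
  stopifnot(is.numeric(r), length(r) == 1L, r >= 0)
  v <- new.env(parent = emptyenv())
  v$r <- as.integer(r)
  v$frozen <- FALSE
  v$vertex_table <- new.env(parent = emptyenv(), hash = TRUE)
  v$edge_table <- new.env(parent = emptyenv(), hash = TRUE)
  v$n_vertex <- 0L
  v$n_edge <- 0L
  class(v) <- "fingerprint_vocab"
  v
}

#' Look up (and possibly assign) fingerprint IDs for signatures
#'
#' @param vocab A [fingerprint_vocab()].
#' @param signatures Character vector of canonical signatures.
#' @param table `"vertex"` or `"edge"`.
#' @return Integer IDs; unseen signatures get fresh IDs while the
#'   vocabulary is open, and the reserved unknown ID 0 once it is frozen.
#' @export
vocab_ids <- function(vocab, signatures, table = c("vertex", "edge")) {
  table <- match.arg(table)
  tab <- if (table == "vertex") vocab$vertex_table else vocab$edge_table
  nfield <- if (table == "vertex") "n_vertex" else "n_edge"
  out <- integer(length(signatures))
  for (k in seq_along(signatures)) {
    s <- signatures[k]
    id <- tab[[s]]
    if (is.null(id)) {
      if (vocab$frozen) {
        id <- 0L
      } else {
        id <- vocab[[nfield]] + 1L
        assign(s, id, envir = tab)
        vocab[[nfield]] <- id
      }
    }
    out[k] <- id
  }
  out
}

#' Freeze a fingerprint vocabulary
#'
#' After freezing, the tables stop growing and unseen signatures map to the
#' unknown ID 0. Models freeze their vocabulary at the end of training so
#' that novel chemistry at prediction time is routed to the trained
#' unknown embedding instead of an out-of-range index.
#'
#' @param vocab A [fingerprint_vocab()].
#' @return The vocabulary, invisibly (modified in place).
#' @export
freeze_vocab <- function(vocab) {
  stopifnot(inherits(vocab, "fingerprint_vocab"))
  vocab$frozen <- TRUE
  invisible(vocab)
}

#' @export
print.fingerprint_vocab <- function(x, ...) {
  cat("<fingerprint_vocab> r =", x$r, "|", x$n_vertex, "vertex +",
      x$n_edge, "edge signatures |",
      if (x$frozen) "frozen" else "open", "\n")
  invisible(x)
}

.vocab_table_as_list <- function(tab) {
  sigs <- ls(tab, sorted = FALSE)
  ids <- vapply(sigs, function(s) tab[[s]], integer(1))
  ord <- order(ids)
  stats::setNames(as.list(ids[ord]), sigs[ord])
}

#' Save / load a fingerprint vocabulary as JSON
#'
#' The file records a format version and the radius `r`; loading a file
#' whose radius differs from `expected_r` is an error, since IDs from
#' different radii are not comparable.
#'
#' @param vocab A [fingerprint_vocab()].
#' @param path File path.
#' @param expected_r If not `NULL`, the radius the caller requires.
#' @return `write_fingerprint_vocab` returns `path` invisibly;
#'   `read_fingerprint_vocab` returns the restored vocabulary with the same
#'   IDs and frozen state.
#' @export
write_fingerprint_vocab <- function(vocab, path) {
  stopifnot(inherits(vocab, "fingerprint_vocab"))
  payload <- list(
    format = "molmiR-fingerprint-vocab",
    version = 1L,
    r = vocab$r,
    frozen = vocab$frozen,
    vertex_table = .vocab_table_as_list(vocab$vertex_table),
    edge_table = .vocab_table_as_list(vocab$edge_table)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = FALSE)
  invisible(path)
}

#' @rdname write_fingerprint_vocab
#' @export
read_fingerprint_vocab <- function(path, expected_r = NULL) {
  payload <- jsonlite::read_json(path)
  if (!identical(payload$format, "molmiR-fingerprint-vocab")) {
    stop("not a fingerprint vocabulary file: ", path, call. = FALSE)
  }
  if (!is.null(expected_r) && as.integer(payload$r) != as.integer(expected_r)) {
    stop("vocabulary radius mismatch: file has r = ", payload$r,
         ", expected r = ", expected_r, call. = FALSE)
  }
  v <- fingerprint_vocab(r = as.integer(payload$r))
  for (s in names(payload$vertex_table)) {
    assign(s, as.integer(payload$vertex_table[[s]]), envir = v$vertex_table)
  }
  for (s in names(payload$edge_table)) {
    assign(s, as.integer(payload$edge_table[[s]]), envir = v$edge_table)
  }
  v$n_vertex <- length(payload$vertex_table)
  v$n_edge <- length(payload$edge_table)
  if (isTRUE(payload$frozen)) v$frozen <- TRUE
  v
}
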