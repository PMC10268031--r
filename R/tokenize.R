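RNA_BASES <- c("A", "C", "G", "U")

#' Enumerate the n-mer token vocabulary
#'
#' All `4^n` words over the RNA alphabet, in lexicographic order. Token IDs
#' are the 1-based positions in this vector; ID 0 is reserved for words
#' containing an ambiguous base (`N`).
#'
#' @param n Word size in bases (default 3).
#' @return Character vector of length `4^n`.
#' @export
kmer_vocabulary <- function(n = 3L) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  n <- as.integer(n)
  grids <- rep(list(RNA_BASES), n)
  m <- do.call(expand.grid, c(rev(grids), stringsAsFactors = FALSE))
  sort(apply(m[, rev(seq_len(n)), drop = FALSE], 1L, paste, collapse = ""))
}

#' Tokenize a miRNA sequence into overlapping n-mer words
#'
#' Splits the sequence into all windows of `n` consecutive bases (stride
#' 1), so a sequence of `s` bases yields `s - n + 1` tokens. `T` is read as
#' `U`, case is ignored, and any word containing `N` maps to the reserved
#' unknown token ID 0.
#'
#' @param sequence RNA sequence string over `A`, `C`, `G`, `U` (`T` and `N`
#'   tolerated).
#' @param n Word size (default 3, small enough that every word is frequent).
#' @param mirna_id Optional identifier carried along, used in error messages.
#' @return An object of class `token_sequence`: list with `mirna_id`,
#'   `tokens` (integer IDs), `n`, and `source_length`.
#' @examples
#' ts <- tokenize("AUGCU")
#' length(ts$tokens)  # 3 == 5 - 3 + 1
#' @export
tokenize <- function(sequence, n = 3L, mirna_id = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- as.integer(n)
  label <- if (is.null(mirna_id)) sequence else mirna_id
  seq <- chartr("Tt", "Uu", toupper(sequence))
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c(RNA_BASES, "N"))
  if (length(bad)) {
    stop("illegal character(s) ", paste(bad, collapse = ", "),
         " in sequence '", label, "'", call. = FALSE)
  }
  s <- length(chars)
  if (s < n) {
    stop("sequence '", label, "' is shorter (", s, ") than the word size (",
         n, ")", call. = FALSE)
  }
  words <- substring(seq, seq_len(s - n + 1L), seq.int(n, s))
  ids <- match(words, kmer_vocabulary(n))
  ids[is.na(ids)] <- 0L  # words containing N
  structure(list(mirna_id = mirna_id, tokens = ids, n = n,
                 source_length = s),
            class = "token_sequence")
}

#' @export
print.token_sequence <- function(x, ...) {
  cat("<token_sequence>", if (!is.null(x$mirna_id)) x$mirna_id else "",
      length(x$tokens), "tokens (n =", x$n, ") from", x$source_length,
      "bases\n")
  invisible(x)
}
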