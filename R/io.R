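#' Read a molecule table (TSV of molecule_id and SMILES)
#'
#' Two tab-separated columns, `molecule_id` and `smiles`; a header line is
#' optional and detected by name.
#'
#' @param path Path to the TSV file.
#' @return Named character vector of SMILES strings, names are molecule IDs.
#' @export
read_molecule_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty molecule table: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad)) {
    stop("malformed molecule table line ", bad[1L], " in ", path,
         call. = FALSE)
  }
  first <- tolower(trimws(fields[[1L]]))
  if (identical(first[1:2], c("molecule_id", "smiles"))) {
    fields <- fields[-1L]
  }
  ids <- vapply(fields, `[[`, "", 1L)
  smi <- vapply(fields, `[[`, "", 2L)
  if (anyDuplicated(ids)) {
    stop("duplicated molecule IDs in ", path, call. = FALSE)
  }
  stats::setNames(smi, ids)
}

#' Write a molecule table
#'
#' @param smiles Named character vector (names = molecule IDs).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_molecule_table <- function(smiles, path) {
  stopifnot(is.character(smiles), !is.null(names(smiles)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("molecule_id\tsmiles",
               paste(names(smiles), smiles, sep = "\t")), con)
  invisible(path)
}

#' Read miRNA sequences from FASTA
#'
#' The record ID up to the first whitespace is the miRNA ID; sequences are
#' upper-cased and DNA-style `T` is mapped to `U`.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of RNA sequences.
#' @export
read_mirna_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(chartr("Tt", "Uu", as.character(set)))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicated miRNA IDs in ", path, call. = FALSE)
  chars <- unique(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE))
  bad <- setdiff(chars, c(RNA_BASES, "N"))
  if (length(bad)) {
    stop("illegal sequence character(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  stats::setNames(seqs, ids)
}

#' Write miRNA sequences as FASTA
#'
#' @param seqs Named character vector of RNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mirna_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a molecule-miRNA association list
#'
#' TSV with columns `molecule_id`, `mirna_id` and an optional binary
#' `label`; when the label column is missing every listed pair is treated
#' as a known (positive) association.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `molecule_id`, `mirna_id`, `label`.
#' @export
read_association_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("empty association table: ", path, call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- tolower(trimws(fields[[1L]]))
  if (identical(first[1:2], c("molecule_id", "mirna_id"))) {
    fields <- fields[-1L]
  }
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop("malformed association line in ", path, call. = FALSE)
  }
  mol <- vapply(fields, `[[`, "", 1L)
  mir <- vapply(fields, `[[`, "", 2L)
  lab <- ifelse(nf >= 3L, vapply(fields, function(f) f[3L], ""), "1")
  lab <- as.integer(lab)
  if (anyNA(lab) || !all(lab %in% c(0L, 1L))) {
    stop("labels must be 0 or 1 in ", path, call. = FALSE)
  }
  data.frame(molecule_id = mol, mirna_id = mir, label = lab,
             stringsAsFactors = FALSE)
}

#' Write an association list
#'
#' @param pairs data.frame with `molecule_id`, `mirna_id` and optionally
#'   `label`.
#' @param path Output path.
#' @param with_label Include the label column (default: present in `pairs`).
#' @return `path`, invisibly.
#' @export
write_association_table <- function(pairs, path,
                                    with_label = "label" %in% names(pairs)) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (with_label) {
    writeLines(c("molecule_id\tmirna_id\tlabel",
                 paste(pairs$molecule_id, pairs$mirna_id, pairs$label,
                       sep = "\t")), con)
  } else {
    writeLines(c("molecule_id\tmirna_id",
                 paste(pairs$molecule_id, pairs$mirna_id, sep = "\t")), con)
  }
  invisible(path)
}

#' Read / write a model configuration as YAML
#'
#' Unknown keys are rejected so that typos in configuration files fail
#' loudly; missing keys fall back to the [molmir_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return For `read_config`, a `molmir_config` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(molmir_config, vals)
}

#' @rdname read_config
#' @param config A [molmir_config()] list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
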