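#' Save / load a trained model as a versioned JSON checkpoint
#'
#' The checkpoint is a single JSON archive holding every parameter tensor
#' (with a shape manifest that is verified on load), the frozen
#' fingerprint vocabulary, the resolved configuration and a hash of it.
#' Text-based on purpose: checkpoints diff cleanly and survive platforms.
#'
#' @param model A trained `molmir_model`.
#' @param path Output path (conventionally `.json`).
#' @return `write_model` returns `path` invisibly; `read_model` returns
#'   the restored `molmir_model` (without the cached training graphs --
#'   molecules are re-parsed on demand at prediction time).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "molmir_model"))
  tensors <- lapply(model$params, function(p) {
    list(dim = if (is.matrix(p)) dim(p) else length(p), data = as.numeric(p))
  })
  payload <- list(
    format = "molmiR-model",
    version = 1L,
    config = unclass(model$config),
    config_hash = .config_hash(model$config),
    shapes = lapply(tensors, `[[`, "dim"),
    params = lapply(tensors, `[[`, "data"),
    vocab = list(r = model$vocab$r,
                 vertex_table = .vocab_table_as_list(model$vocab$vertex_table),
                 edge_table = .vocab_table_as_list(model$vocab$edge_table)),
    train_pairs = model$train_pairs,
    log = model$log
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "molmiR-model")) {
    stop("not a model checkpoint: ", path, call. = FALSE)
  }
  config <- do.call(molmir_config, as.list(payload$config))
  if (!identical(unname(payload$config_hash), .config_hash(config))) {
    stop("checkpoint configuration hash mismatch in ", path, call. = FALSE)
  }
  params <- vector("list", length(payload$params))
  names(params) <- names(payload$params)
  for (nm in names(params)) {
    dm <- payload$shapes[[nm]]
    x <- payload$params[[nm]]
    if (length(x) != prod(dm)) {
      stop("tensor ", nm, " does not match its shape manifest", call. = FALSE)
    }
    params[[nm]] <- if (length(dm) == 2L) matrix(x, dm[1], dm[2]) else x
  }
  attr(params, "d") <- config$d
  attr(params, "L") <- config$L
  attr(params, "w") <- config$w
  class(params) <- "model_params"
  vocab <- fingerprint_vocab(r = as.integer(payload$vocab$r))
  for (s in names(payload$vocab$vertex_table)) {
    assign(s, as.integer(payload$vocab$vertex_table[[s]]),
           envir = vocab$vertex_table)
  }
  for (s in names(payload$vocab$edge_table)) {
    assign(s, as.integer(payload$vocab$edge_table[[s]]),
           envir = vocab$edge_table)
  }
  vocab$n_vertex <- length(payload$vocab$vertex_table)
  vocab$n_edge <- length(payload$vocab$edge_table)
  freeze_vocab(vocab)
  structure(list(params = params, vocab = vocab, config = config,
                 graphs = list(), tokens = list(),
                 train_pairs = as.data.frame(payload$train_pairs),
                 log = as.data.frame(payload$log)),
            class = "molmir_model")
}
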