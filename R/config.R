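#' Model and training configuration
#'
#' Collects every tunable of the pipeline in one validated list. Defaults:
#' \describe{
#'   \item{r = 2}{fingerprint neighborhood radius (bonds).}
#'   \item{n = 3}{miRNA word size in bases.}
#'   \item{w = 5}{CNN window: consecutive words concatenated per position.}
#'   \item{d = 16}{embedding width shared by both encoders.}
#'   \item{T = 2}{GNN vertex/edge update rounds.}
#'   \item{L = 2}{CNN filter layers.}
#'   \item{attention = TRUE}{use the attention-weighted sequence readout;
#'     `FALSE` falls back to the plain mean readout (ablation).}
#'   \item{strip_hydrogens = TRUE}{heavy-atom molecular graphs.}
#'   \item{ratio = 1}{negatives sampled per positive.}
#'   \item{optimizer = "adam"}{per-pair stochastic updates; `"sgd"`
#'     selects plain momentum SGD (`momentum` applies only there).}
#'   \item{epochs = 12, lr = 0.003}{training schedule.}
#'   \item{seed = 1}{master seed for initialization and shuffling.}
#' }
#'
#' @param ... Named overrides of the defaults above.
#' @return A classed list (`molmir_config`).
#' @export
molmir_config <- function(...) {
  cfg <- list(
    r = 2L, n = 3L, w = 5L, d = 16L, T = 2L, L = 2L,
    attention = TRUE, strip_hydrogens = TRUE,
    ratio = 1, optimizer = "adam", epochs = 12L, lr = 0.003,
    momentum = 0.9, seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots)))) {
      stop("configuration overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(dots)] <- dots
  }
  for (k in c("r", "n", "w", "d", "T", "L", "epochs", "seed")) {
    cfg[[k]] <- as.integer(cfg[[k]])
  }
  stopifnot(cfg$r >= 0, cfg$n >= 1, cfg$w >= 1, cfg$d >= 1, cfg$T >= 0,
            cfg$L >= 1, cfg$ratio > 0, cfg$epochs >= 0, cfg$lr > 0,
            cfg$momentum >= 0, cfg$momentum < 1,
            cfg$optimizer %in% c("adam", "sgd"))
  structure(cfg, class = "molmir_config")
}

#' @export
print.molmir_config <- function(x, ...) {
  cat("<molmir_config>\n")
  for (k in names(x)) cat(" ", k, "=", format(x[[k]]), "\n")
  invisible(x)
}

# Names of the conv layer tensors for a given layer count.
.conv_names <- function(L) {
  list(W = paste0("W_conv", seq_len(L)), b = paste0("b_conv", seq_len(L)))
}

#' Initialize all learned tensors of the model
#'
#' Embedding tables get one extra leading row for the reserved unknown ID
#' 0 (trained like any other row). All tensors are drawn from a zero-mean
#' uniform distribution scaled by `1/sqrt(d)`.
#'
#' Biases are drawn from the same distribution rather than set to zero:
#' with zero biases, a window whose hidden vector is fully ReLU-dead would
#' put later pre-activations exactly at the ReLU kink, where gradients are
#' not defined.
#'
#' @param n_vertex_ids,n_edge_ids Sizes of the fingerprint vocabularies
#'   (excluding the unknown ID).
#' @param n_tokens Size of the word vocabulary (excluding the unknown ID).
#' @param config A [molmir_config()].
#' @param seed Integer seed for the draw (default: `config$seed`).
#' @return Named list of matrices/vectors (class `model_params`):
#'   `vertex_embedding`, `edge_embedding`, `W_neighbor`, `b_neighbor`,
#'   `W_side`, `b_side`, `word_embedding`, `W_conv1..L`, `b_conv1..L`,
#'   `W_inter`, `b_inter`, `W_output`, `b_output`.
#' @export
init_model_params <- function(n_vertex_ids, n_edge_ids, n_tokens,
                              config = molmir_config(),
                              seed = config$seed) {
  d <- config$d
  w <- config$w
  L <- config$L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  u <- function(nr, nc) {
    matrix(stats::runif(nr * nc, -1, 1) / sqrt(d), nr, nc)
  }
  uv <- function(len) as.numeric(u(1L, len))
  p <- list(
    vertex_embedding = u(n_vertex_ids + 1L, d),
    edge_embedding = u(n_edge_ids + 1L, d),
    W_neighbor = u(d, 2L * d),
    b_neighbor = uv(d),
    W_side = u(d, d),
    b_side = uv(d),
    word_embedding = u(n_tokens + 1L, d)
  )
  cn <- .conv_names(L)
  p[[cn$W[1L]]] <- u(d, d * w)
  p[[cn$b[1L]]] <- uv(d)
  for (l in seq_len(L)[-1L]) {
    p[[cn$W[l]]] <- u(d, d)
    p[[cn$b[l]]] <- uv(d)
  }
  p$W_inter <- u(d, d)
  p$b_inter <- uv(d)
  p$W_output <- u(2L, 2L * d)
  p$b_output <- uv(2L)
  structure(p, class = "model_params", d = d, L = L, w = w)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}
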