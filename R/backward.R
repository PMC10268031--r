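# Analytic gradients of the cross-entropy loss for one pair, mirroring
# forward_pair(keep = TRUE). Gradients are returned as a dense named list
# with exactly the shapes of the parameter list.

.scatter_add <- function(M, idx, nr) {
  out <- matrix(0, nr, ncol(M))
  if (length(idx)) {
    acc <- rowsum(M, idx)
    out[as.integer(rownames(acc)), ] <- acc
  }
  out
}

.zero_like <- function(params) {
  g <- lapply(params, function(p) {
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  })
  attributes(g) <- attributes(params)
  g
}

pair_loss <- function(prob, label) {
  -log(prob[label + 1L])
}

backward_pair <- function(fw, label, params, config) {
  cache <- fw$cache
  d <- attr(params, "d")
  L <- attr(params, "L")
  w <- attr(params, "w")
  gr <- .zero_like(params)

  # ---- output head ----
  target <- c(0, 0)
  target[label + 1L] <- 1
  dz <- cache$p - target
  gr$W_output <- dz %o% c(cache$y_mi, cache$y_sm)
  gr$b_output <- dz
  dcat <- as.numeric(crossprod(params$W_output, dz))
  dy_mi <- dcat[seq_len(d)]
  dy_sm <- dcat[d + seq_len(d)]

  # ---- attention / readout ----
  CL <- cache$C
  nwin <- nrow(CL)
  if (config$attention) {
    att <- cache$att
    h <- att$h
    h_sm <- att$h_sm
    alpha <- att$alpha
    dh <- alpha %o% dy_mi
    dalpha <- as.numeric(h %*% dy_mi)
    ds <- dalpha * alpha * (1 - alpha)
    dh <- dh + ds %o% h_sm
    dh_sm <- as.numeric(crossprod(h, ds))
    dpre_h <- dh * (h > 0)
    gr$W_inter <- gr$W_inter + crossprod(dpre_h, CL)
    gr$b_inter <- gr$b_inter + colSums(dpre_h)
    dCL <- dpre_h %*% params$W_inter
    dpre_sm <- dh_sm * (h_sm > 0)
    gr$W_inter <- gr$W_inter + dpre_sm %o% cache$y_sm
    gr$b_inter <- gr$b_inter + dpre_sm
    dy_sm <- dy_sm + as.numeric(crossprod(params$W_inter, dpre_sm))
  } else {
    dCL <- matrix(dy_mi / nwin, nwin, d, byrow = TRUE)
  }

  # ---- conv stack ----
  cn <- .conv_names(L)
  dC <- dCL
  for (l in rev(seq_len(L))) {
    Cl <- cache$layers[[l]]
    Cprev <- if (l == 1L) cache$C0 else cache$layers[[l - 1L]]
    dpre <- dC * (Cl > 0)
    gr[[cn$W[l]]] <- gr[[cn$W[l]]] + crossprod(dpre, Cprev)
    gr[[cn$b[l]]] <- gr[[cn$b[l]]] + colSums(dpre)
    dC <- dpre %*% params[[cn$W[l]]]
  }
  # dC is now the gradient w.r.t. the window matrix C0 (nwin x d*w)
  ntok <- length(cache$ts$tokens)
  dX <- matrix(0, ntok, d)
  for (k in seq_len(w) - 1L) {
    rows <- seq_len(nwin) + k
    dX[rows, ] <- dX[rows, ] + dC[, k * d + seq_len(d), drop = FALSE]
  }
  gr$word_embedding <- .scatter_add(dX, cache$ts$tokens + 1L,
                                    nrow(params$word_embedding))

  # ---- molecule encoder ----
  g <- cache$mol
  enc <- cache$enc
  nv <- nrow(g$atoms)
  ne <- nrow(g$bonds)
  dV <- matrix(dy_sm / nv, nv, d, byrow = TRUE)
  dE <- matrix(0, max(ne, 0L), d)
  for (t in rev(seq_len(config$T))) {
    Vt1 <- enc$V[[t + 1L]]
    Et1 <- enc$E[[t + 1L]]
    Vt <- enc$V[[t]]
    Et <- enc$E[[t]]
    if (ne > 0L) {
      # edge update: E_{t+1} = sigmoid(E_t + G_t), G_t from new vertices
      dPe <- dE * Et1 * (1 - Et1)
      dE_t <- dPe
      dQg <- dPe * (enc$G[[t]] > 0)
      gr$W_side <- gr$W_side + crossprod(dQg, g$Gend %*% Vt1)
      gr$b_side <- gr$b_side + colSums(dQg)
      dV <- dV + crossprod(g$Gend, dQg %*% params$W_side)
    } else {
      dE_t <- dE
    }
    # vertex update: V_{t+1} = sigmoid(V_t + S_t)
    dPv <- dV * Vt1 * (1 - Vt1)
    dV_t <- dPv
    if (ne > 0L) {
      dH <- dPv[g$ddst, , drop = FALSE]
      dQh <- dH * (enc$H[[t]] > 0)
      A <- cbind(Vt[g$dsrc, , drop = FALSE], Et[g$deid, , drop = FALSE])
      gr$W_neighbor <- gr$W_neighbor + crossprod(dQh, A)
      gr$b_neighbor <- gr$b_neighbor + colSums(dQh)
      dA <- dQh %*% params$W_neighbor
      dV_t <- dV_t + g$Gsrc %*% dA[, seq_len(d), drop = FALSE]
      dE_t <- dE_t + g$Geid %*% dA[, d + seq_len(d), drop = FALSE]
    }
    dV <- dV_t
    dE <- dE_t
  }
  gr$vertex_embedding <- .scatter_add(dV, enc$vrow,
                                      nrow(params$vertex_embedding))
  if (ne > 0L) {
    gr$edge_embedding <- .scatter_add(dE, enc$erow,
                                      nrow(params$edge_embedding))
  }
  gr
}

#' Compare analytic and finite-difference gradients on one pair
#'
#' Perturbs every entry of every parameter tensor (central differences)
#' and compares the numeric gradient of the pair's cross-entropy loss with
#' the gradient computed by the model's backward pass. Intended for small
#' configurations; cost is two forward passes per parameter entry.
#'
#' @param mol Fingerprinted `molecular_graph`.
#' @param ts A [tokenize()]d sequence.
#' @param label 0 or 1.
#' @param params [init_model_params()] list.
#' @param config [molmir_config()].
#' @param eps Finite-difference step (default 1e-5).
#' @return data.frame with one row per parameter tensor: its name and the
#'   relative error `|g_num - g_ana| / (|g_num| + |g_ana|)` in Frobenius
#'   norm (0 when both gradients vanish).
#' @export
gradient_check <- function(mol, ts, label, params, config, eps = 1e-5) {
  fw <- forward_pair(mol, ts, params, config, keep = TRUE)
  ana <- backward_pair(fw, label, params, config)
  loss_at <- function(p) {
    pair_loss(forward_pair(mol, ts, p, config)$prob, label)
  }
  rows <- lapply(names(params), function(nm) {
    p <- params
    num <- params[[nm]]
    num[] <- 0
    for (i in seq_along(params[[nm]])) {
      p[[nm]][i] <- params[[nm]][i] + eps
      up <- loss_at(p)
      p[[nm]][i] <- params[[nm]][i] - eps
      dn <- loss_at(p)
      p[[nm]][i] <- params[[nm]][i]
      num[i] <- (up - dn) / (2 * eps)
    }
    na <- sqrt(sum(ana[[nm]]^2))
    nn <- sqrt(sum(num^2))
    dd <- sqrt(sum((ana[[nm]] - num)^2))
    rel <- if (na + nn == 0) 0 else dd / (na + nn)
    data.frame(tensor = nm, rel_err = rel, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
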