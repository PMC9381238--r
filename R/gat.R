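# Graph attention classifier (two attention layers, two heads: hidden
# concatenated, output averaged). Attention per node i over j in N(i) u
# {i}: e_ij = LeakyReLU(a_src . (W h_i) + a_dst . (W h_j)), softmax over
# j, features aggregated by the attention weights. Forward, exact
# backward and Adam training are hand-written, mirroring the GCN module.

leaky_relu <- function(x, slope = 0.2) pmax(x, 0) + slope * pmin(x, 0)

# Directed edge index with self-loops (node src attends over dst), plus
# precomputed aggregation machinery reused every epoch: sparse
# edge-to-node summation operators, a padded per-source index matrix for
# segmented maxima, and value-slot maps for the attention matrix and its
# transpose (their sparsity patterns never change).
gat_edge_index <- function(graph) {
  e <- graph$edges
  src <- c(e$i, e$j, seq_len(graph$n))
  dst <- c(e$j, e$i, seq_len(graph$n))
  ord <- order(src, dst)
  src <- src[ord]; dst <- dst[ord]
  E <- length(src); n <- graph$n
  groups <- split(seq_len(E), src)
  maxdeg <- max(lengths(groups))
  padidx <- matrix(1L, n, maxdeg)
  padmask <- matrix(TRUE, n, maxdeg)
  for (g in seq_len(n)) {
    ix <- groups[[g]]
    padidx[g, seq_along(ix)] <- ix
    padmask[g, seq_along(ix)] <- FALSE
  }
  Ssrc <- Matrix::sparseMatrix(i = src, j = seq_len(E), x = 1, dims = c(n, E))
  Sdst <- Matrix::sparseMatrix(i = dst, j = seq_len(E), x = 1, dims = c(n, E))
  SA0 <- Matrix::sparseMatrix(i = src, j = dst, x = seq_len(E), dims = c(n, n))
  TA0 <- Matrix::sparseMatrix(i = dst, j = src, x = seq_len(E), dims = c(n, n))
  list(src = src, dst = dst, n = n, E = E,
       padidx = padidx, padmask = padmask,
       Ssrc = to_dgc(Ssrc), Sdst = to_dgc(Sdst),
       SA = to_dgc(SA0), SA_map = as.integer(SA0@x),
       TA = to_dgc(TA0), TA_map = as.integer(TA0@x))
}

# Segmented maximum of an edge vector over source-node groups.
seg_max <- function(x, ei) {
  Em <- matrix(x[ei$padidx], ei$n)
  Em[ei$padmask] <- -Inf
  M <- Em[, 1]
  for (j in seq_len(ncol(Em))[-1]) M <- pmax(M, Em[, j])
  M
}

#' Initialize graph-attention parameters
#'
#' Two layers: `heads` heads of width `hidden/heads` concatenated, then
#' `heads` output heads averaged into 2 classes. Each head carries a
#' Glorot-uniform projection `W` and attention vectors `a_src`, `a_dst`.
#'
#' @param d_in Input feature dimension.
#' @param hidden Concatenated hidden width (default 64); must be a
#'   multiple of `heads`.
#' @param heads Attention heads (default 2).
#' @param seed Integer seed.
#' @param d_out Output classes (default 2).
#' @return A `gat_params` list (`layers`, each with `heads`).
#' @export
gat_init <- function(d_in, hidden = 64, heads = 2, seed = 1L, d_out = 2L) {
  stopifnot(hidden %% heads == 0)
  set.seed(seed)
  h1 <- hidden %/% heads
  mk_head <- function(fi, fo)
    list(W = glorot(fi, fo),
         a_src = runif(fo, -sqrt(6 / (fo + 1)), sqrt(6 / (fo + 1))),
         a_dst = runif(fo, -sqrt(6 / (fo + 1)), sqrt(6 / (fo + 1))))
  # combine rule is positional: hidden layer concatenates its heads, the
  # output layer averages them (keeps the parameter list purely numeric)
  structure(list(layers = list(
    list(heads = lapply(seq_len(heads), function(h) mk_head(d_in, h1))),
    list(heads = lapply(seq_len(heads), function(h) mk_head(hidden, d_out))))),
    class = "gat_params")
}

gat_head_forward <- function(H, head, ei) {
  G <- H %*% head$W
  s <- drop(G %*% head$a_src)
  t <- drop(G %*% head$a_dst)
  epre <- s[ei$src] + t[ei$dst]
  eact <- leaky_relu(epre)
  a_un <- exp(eact - seg_max(eact, ei)[ei$src])
  denom <- drop(as.matrix(ei$Ssrc %*% a_un))
  alpha <- a_un / denom[ei$src]
  SA <- ei$SA
  SA@x <- alpha[ei$SA_map]
  list(O = as.matrix(SA %*% G), G = G, epre = epre, alpha = alpha)
}

gat_forward_full <- function(graph, X, params, ei = NULL) {
  if (is.null(ei)) ei <- gat_edge_index(graph)
  H <- X
  caches <- vector("list", length(params$layers))
  L <- length(params$layers)
  for (l in seq_len(L)) {
    layer <- params$layers[[l]]
    hc <- lapply(layer$heads, function(hd) gat_head_forward(H, hd, ei))
    O <- lapply(hc, `[[`, "O")
    Z <- if (l < L) do.call(cbind, O)                 # concat hidden heads
         else Reduce(`+`, O) / length(O)              # average output heads
    if (!all(is.finite(Z))) stop("non-finite intermediate at attention layer ", l)
    caches[[l]] <- list(H_in = H, heads = hc, Z = Z)
    H <- if (l < L) pmax(Z, 0) else Z
  }
  list(logp = log_softmax_rows(H), caches = caches, ei = ei)
}

#' Graph-attention forward pass
#'
#' @param graph A `trial_graph`.
#' @param X n x d feature matrix.
#' @param params A `gat_params`.
#' @return n x 2 matrix of log-probabilities.
#' @export
gat_forward <- function(graph, X, params) {
  gat_forward_full(graph, X, params)$logp
}

gat_objective <- function(graph, X, params, labels, mask, weight_decay = 0) {
  nll_loss(gat_forward(graph, X, params), labels, mask) +
    weight_decay / 2 * sum(vapply(unlist(lapply(params$layers, `[[`, "heads"),
                                         recursive = FALSE),
                                  function(hd) sum(hd$W^2), numeric(1)))
}

gat_head_backward <- function(dO, cache, head, H_in, ei) {
  G <- cache$G
  d_alpha <- rowSums(dO[ei$src, , drop = FALSE] * G[ei$dst, , drop = FALSE])
  TA <- ei$TA
  TA@x <- cache$alpha[ei$TA_map]
  dG <- as.matrix(TA %*% dO)
  sdot <- drop(as.matrix(ei$Ssrc %*% (cache$alpha * d_alpha)))
  de <- cache$alpha * (d_alpha - sdot[ei$src])
  depre <- de * (0.2 + 0.8 * (cache$epre > 0))
  ds <- drop(as.matrix(ei$Ssrc %*% depre))
  dt <- drop(as.matrix(ei$Sdst %*% depre))
  dG <- dG + outer(ds, head$a_src) + outer(dt, head$a_dst)
  list(W = crossprod(H_in, dG),
       a_src = drop(crossprod(G, ds)),
       a_dst = drop(crossprod(G, dt)),
       dH = dG %*% t(head$W))
}

#' Exact gradients of the graph-attention objective
#'
#' Backpropagates the masked negative log-likelihood (plus L2 decay on
#' the projection matrices) through attention softmax, LeakyReLU scores
#' and aggregation.
#'
#' @inheritParams gat_forward
#' @param labels Integer 0/1 vector.
#' @param mask Node mask contributing to the loss.
#' @param weight_decay L2 coefficient on projection matrices.
#' @param ei Optional precomputed edge index (internal reuse).
#' @return List with `grads` (shape of `params`) and `loss`.
#' @export
gat_backward <- function(graph, X, params, labels, mask, weight_decay = 0,
                         ei = NULL) {
  fw <- gat_forward_full(graph, X, params, ei)
  ei <- fw$ei
  idx <- if (is.logical(mask)) which(mask) else as.integer(mask)
  m <- length(idx)
  loss <- nll_loss(fw$logp, labels, idx) +
    weight_decay / 2 * sum(vapply(unlist(lapply(params$layers, `[[`, "heads"),
                                         recursive = FALSE),
                                  function(hd) sum(hd$W^2), numeric(1)))

  n <- nrow(X)
  Y <- matrix(0, n, ncol(fw$logp))
  Y[cbind(idx, labels[idx] + 1L)] <- 1
  dZ <- matrix(0, n, ncol(fw$logp))
  dZ[idx, ] <- exp(fw$logp[idx, , drop = FALSE])
  dZ <- (dZ - Y) / m

  grads <- params
  L <- length(params$layers)
  dH_out <- dZ
  for (l in rev(seq_len(L))) {
    layer <- params$layers[[l]]
    cache <- fw$caches[[l]]
    if (l < L) dH_out <- dH_out * (cache$Z > 0)
    nh <- length(layer$heads)
    dH_in <- 0
    for (h in seq_len(nh)) {
      dO <- if (l < L) {
        d <- ncol(cache$heads[[h]]$O)
        dH_out[, ((h - 1) * d + 1):(h * d), drop = FALSE]
      } else dH_out / nh
      hb <- gat_head_backward(dO, cache$heads[[h]], layer$heads[[h]],
                              cache$H_in, ei)
      grads$layers[[l]]$heads[[h]] <-
        list(W = hb$W + weight_decay * layer$heads[[h]]$W,
             a_src = hb$a_src, a_dst = hb$a_dst)
      dH_in <- dH_in + hb$dH
    }
    dH_out <- dH_in
  }
  list(grads = grads, loss = loss)
}

#' Train the graph-attention classifier transductively
#'
#' Same protocol as [train_gcn()]: full-batch Adam on the budgeted
#' negative log-likelihood, deterministic given `config$seed`.
#'
#' @inheritParams train_gcn
#' @param heads Attention heads (default 2).
#' @return List with trained `params`, `loss_history`, `config`.
#' @export
train_gat <- function(graph, features, labels, train_mask, config, heads = 2) {
  idx <- if (is.logical(train_mask)) which(train_mask) else as.integer(train_mask)
  if (length(idx) != config$budget)
    stop("train_mask size (", length(idx), ") != budget (", config$budget, ")")
  params <- gat_init(ncol(features), config$hidden, heads, seed = config$seed)
  ei <- gat_edge_index(graph)
  state <- adam_init(params)
  history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    g <- gat_backward(graph, features, params, labels, idx,
                      config$weight_decay, ei = ei)
    if (!is.finite(g$loss))
      stop("training diverged (non-finite loss) at epoch ", ep)
    history[ep] <- g$loss
    upd <- adam_step(params, g$grads, state, config)
    params <- upd$params
    state <- upd$state
  }
  list(params = params, loss_history = history, config = config)
}

#' Predict with a trained graph-attention classifier
#' @inheritParams predict_gcn
#' @return List with integer `label` and positive-class `prob`.
#' @export
predict_gat <- function(params, graph, features) {
  logp <- gat_forward(graph, features, params)
  list(label = as.integer(logp[, 2] > logp[, 1]), prob = exp(logp[, 2]))
}
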