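# From-scratch graph convolutional classifier. Architecture: an input
# layer, four hidden layers and an output layer (five weight matrices,
# d_in -> h, h -> h x3, h -> 2). Every layer propagates through the
# renormalized operator A_hat; ReLU after the four hidden transforms,
# row-wise log-softmax at the output. Trained full-batch (transductive)
# with negative log-likelihood on a budgeted label mask, L2 weight decay
# on the weight matrices, and hand-written bias-corrected Adam.

#' Training configuration for the graph classifier
#'
#' @param budget Number of labelled nodes contributing to the loss.
#' @param hidden Hidden width of the four hidden layers (default 64).
#' @param lr Adam learning rate (default 0.01).
#' @param epochs Full-batch epochs (default 200).
#' @param weight_decay L2 penalty coefficient on weight matrices
#'   (default 5e-4; biases unpenalized).
#' @param beta1,beta2,eps Adam moment decays and stabilizer.
#' @param seed Integer seed for initialization.
#' @return A `train_config` list.
#' @export
train_config <- function(budget, hidden = 64, lr = 0.01, epochs = 200,
                         weight_decay = 5e-4, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, seed = 1L) {
  stopifnot(budget >= 1, hidden >= 1, epochs >= 1, lr > 0,
            weight_decay >= 0)
  structure(list(budget = as.integer(budget), hidden = as.integer(hidden),
                 lr = lr, epochs = as.integer(epochs),
                 weight_decay = weight_decay, beta1 = beta1, beta2 = beta2,
                 eps = eps, seed = as.integer(seed)),
            class = "train_config")
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Initialize graph-classifier parameters
#'
#' Glorot-uniform weight matrices (d_in -> h, h -> h x3, h -> 2) and
#' zero biases, drawn under `seed`.
#'
#' @param d_in Input feature dimension (39, or 38 post-ablation).
#' @param hidden Hidden width.
#' @param seed Integer seed.
#' @param d_out Output classes (default 2).
#' @return A `gcn_params` list with fields `W` (5 matrices) and `b`.
#' @export
gcn_init <- function(d_in, hidden = 64, seed = 1L, d_out = 2L) {
  set.seed(seed)
  dims <- c(d_in, hidden, hidden, hidden, hidden, d_out)
  W <- lapply(seq_len(5), function(l) glorot(dims[l], dims[l + 1]))
  b <- lapply(seq_len(5), function(l) numeric(dims[l + 1]))
  structure(list(W = W, b = b), class = "gcn_params")
}

log_softmax_rows <- function(Z) {
  m <- Z[, 1]
  for (j in seq_len(ncol(Z))[-1]) m <- pmax(m, Z[, j])
  Zs <- Z - m
  Zs - log(rowSums(exp(Zs)))
}

add_bias <- function(P, b) P + rep(b, each = nrow(P))

# Sparse-dense product as a plain dense matrix.
spmm_d <- function(A, B) {
  if (is.matrix(A)) return(A %*% B)
  as.matrix(A %*% B)
}

# Forward pass retaining intermediates for backpropagation. M1 may carry
# a precomputed A_hat %*% X (parameter-independent, so training loops
# compute it once).
gcn_forward_full <- function(A_hat, X, params, M1 = NULL) {
  H <- X
  M <- vector("list", 5); P <- vector("list", 5); Hs <- vector("list", 6)
  Hs[[1]] <- X
  for (l in 1:5) {
    M[[l]] <- if (l == 1 && !is.null(M1)) M1 else spmm_d(A_hat, H)
    P[[l]] <- add_bias(M[[l]] %*% params$W[[l]], params$b[[l]])
    if (!is.finite(sum(P[[l]])))
      stop("non-finite intermediate at layer ", l)
    H <- if (l < 5) P[[l]] * (P[[l]] > 0) else P[[l]]
    Hs[[l + 1]] <- H
  }
  list(logp = log_softmax_rows(Hs[[6]]), M = M, P = P, H = Hs)
}

#' Graph-classifier forward pass
#'
#' `H0 = X`; `H(l+1) = ReLU(A_hat H(l) W(l) + b(l))` for the four hidden
#' layers; output `log-softmax(A_hat H4 W5 + b5)` row-wise.
#'
#' @param A_hat Sparse symmetric propagation operator (n x n).
#' @param X Feature matrix (n x d_in).
#' @param params A `gcn_params`.
#' @return n x 2 matrix of log-probabilities (rows exponentiate to sum
#'   to 1).
#' @export
gcn_forward <- function(A_hat, X, params) {
  gcn_forward_full(A_hat, X, params)$logp
}

#' Negative log-likelihood loss over a node mask
#'
#' Mean over masked nodes of minus the log-probability at the true class.
#'
#' @param log_probs n x 2 log-probability matrix.
#' @param labels Integer 0/1 vector of length n.
#' @param mask Logical or integer index selecting at least one node.
#' @return Scalar loss.
#' @export
nll_loss <- function(log_probs, labels, mask) {
  idx <- if (is.logical(mask)) which(mask) else as.integer(mask)
  if (length(idx) == 0) stop("empty mask")
  -mean(log_probs[cbind(idx, labels[idx] + 1L)])
}

# Training objective: NLL + (wd/2) * sum ||W||^2 (biases unpenalized).
gcn_objective <- function(A_hat, X, params, labels, mask, weight_decay) {
  nll_loss(gcn_forward(A_hat, X, params), labels, mask) +
    weight_decay / 2 * sum(vapply(params$W, function(w) sum(w^2), numeric(1)))
}

#' Exact gradients of the graph-classifier objective
#'
#' Backpropagates the masked negative log-likelihood plus the L2
#' weight-decay term through the five propagation layers. Matches central
#' finite differences on small instances.
#'
#' @inheritParams gcn_forward
#' @param labels Integer 0/1 vector.
#' @param mask Node mask contributing to the loss.
#' @param weight_decay L2 coefficient on weight matrices.
#' @return List with gradient fields `W`, `b` mirroring `params`, plus
#'   the forward `loss`.
#' @export
gcn_backward <- function(A_hat, X, params, labels, mask, weight_decay = 0,
                         M1 = NULL) {
  fw <- gcn_forward_full(A_hat, X, params, M1)
  idx <- if (is.logical(mask)) which(mask) else as.integer(mask)
  n <- nrow(X); m <- length(idx)
  loss <- nll_loss(fw$logp, labels, mask) +
    weight_decay / 2 * sum(vapply(params$W, function(w) sum(w^2), numeric(1)))

  Y <- matrix(0, n, ncol(fw$logp))
  Y[cbind(idx, labels[idx] + 1L)] <- 1
  dZ <- matrix(0, n, ncol(fw$logp))
  dZ[idx, ] <- exp(fw$logp[idx, , drop = FALSE])
  dZ <- (dZ - Y) / m                      # rows outside the mask stay zero

  dW <- vector("list", 5); db <- vector("list", 5)
  dP <- dZ
  for (l in 5:1) {
    dW[[l]] <- crossprod(fw$M[[l]], dP) + weight_decay * params$W[[l]]
    db[[l]] <- colSums(dP)
    if (l > 1) {
      dH <- spmm_d(A_hat, dP %*% t(params$W[[l]]))
      dP <- dH * (fw$P[[l - 1]] > 0)
    }
  }
  list(W = dW, b = db, loss = loss)
}

# Adam ----------------------------------------------------------------------

#' Initialize Adam optimizer state
#' @param params A parameter list (any nesting of numeric arrays).
#' @return An `adam_state` with zeroed first/second moments and step 0.
#' @export
adam_init <- function(params) {
  theta <- unlist(params, use.names = FALSE)
  structure(list(m = numeric(length(theta)), v = numeric(length(theta)),
                 step = 0L),
            class = "adam_state")
}

#' One bias-corrected Adam update
#'
#' Standard Adam: moment accumulation, bias correction, and the update
#' `theta <- theta - lr * m_hat / (sqrt(v_hat) + eps)`.
#'
#' @param params Parameter list (numeric arrays, any nesting).
#' @param grads Gradient list of identical shape.
#' @param state An `adam_state` from [adam_init()].
#' @param config A [train_config()] (fields `lr`, `beta1`, `beta2`, `eps`).
#' @return List with updated `params` and `state`.
#' @export
adam_step <- function(params, grads, state, config) {
  theta <- unlist(params, use.names = FALSE)
  g <- unlist(grads, use.names = FALSE)
  stopifnot(length(theta) == length(g))
  state$step <- state$step + 1L
  state$m <- config$beta1 * state$m + (1 - config$beta1) * g
  state$v <- config$beta2 * state$v + (1 - config$beta2) * g^2
  m_hat <- state$m / (1 - config$beta1^state$step)
  v_hat <- state$v / (1 - config$beta2^state$step)
  theta <- theta - config$lr * m_hat / (sqrt(v_hat) + config$eps)
  list(params = refill_params(theta, params), state = state)
}

# Rebuild a nested parameter list from a flat vector (unlist order).
refill_params <- function(theta, skeleton) {
  pos <- 0L
  fill <- function(x) {
    if (is.list(x)) return(lapply(x, fill))
    k <- length(x)
    out <- theta[pos + seq_len(k)]
    pos <<- pos + k
    dim(out) <- dim(x)
    out
  }
  out <- fill(unclass(skeleton))
  attributes(out) <- attributes(skeleton)
  out
}

#' Train the graph classifier transductively
#'
#' Full-batch training: the whole graph and feature matrix are visible;
#' only the `train_mask` nodes (the label budget) contribute to the loss.
#' Deterministic given `config$seed` (Glorot initialization).
#'
#' @param graph A `trial_graph`.
#' @param features n x d feature matrix (row order = node order).
#' @param labels Integer 0/1 vector of length n.
#' @param train_mask Logical or index mask of budgeted labelled nodes;
#'   its size must equal `config$budget`.
#' @param config A [train_config()].
#' @return List with trained `params`, the per-epoch `loss_history`, and
#'   `config`.
#' @export
train_gcn <- function(graph, features, labels, train_mask, config) {
  idx <- if (is.logical(train_mask)) which(train_mask) else as.integer(train_mask)
  if (length(idx) != config$budget)
    stop("train_mask size (", length(idx), ") != budget (", config$budget, ")")
  params <- gcn_init(ncol(features), config$hidden, seed = config$seed)
  state <- adam_init(params)
  history <- numeric(config$epochs)
  M1 <- as.matrix(graph$A_hat %*% features)
  for (ep in seq_len(config$epochs)) {
    g <- gcn_backward(graph$A_hat, features, params, labels, idx,
                      config$weight_decay, M1 = M1)
    if (!is.finite(g$loss))
      stop("training diverged (non-finite loss) at epoch ", ep)
    history[ep] <- g$loss
    upd <- adam_step(params, list(W = g$W, b = g$b), state, config)
    params <- upd$params
    state <- upd$state
  }
  list(params = params, loss_history = history, config = config)
}

#' Predict node classes and positive-class probabilities
#'
#' Argmax class per node (ties go to class 0) and the probability of the
#' positive class ("continuing test").
#'
#' @param params Trained `gcn_params`.
#' @param graph A `trial_graph`.
#' @param features n x d feature matrix.
#' @return List with integer `label` (0/1) and numeric `prob` (class-1
#'   probability).
#' @export
predict_gcn <- function(params, graph, features) {
  logp <- gcn_forward(graph$A_hat, features, params)
  list(label = as.integer(logp[, 2] > logp[, 1]), prob = exp(logp[, 2]))
}
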