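# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately use plain loops / dense algebra and
# share no code with the functions they validate.

# Renormalized operator from the explicit dense formula.
oracle_ahat <- function(A) {
  A <- as.matrix(A)
  At <- A + diag(nrow(A))
  d <- rowSums(At)
  Dm <- diag(1 / sqrt(d), nrow(A))
  Dm %*% At %*% Dm
}

# Dense GCN forward: explicit matrix products, no sparsity, own softmax.
oracle_gcn_forward <- function(A_hat, X, params) {
  A <- as.matrix(A_hat)
  H <- as.matrix(X)
  for (l in 1:5) {
    P <- A %*% H %*% params$W[[l]]
    for (j in seq_along(params$b[[l]])) P[, j] <- P[, j] + params$b[[l]][j]
    H <- if (l < 5) ifelse(P > 0, P, 0) else P
  }
  out <- matrix(NA_real_, nrow(H), ncol(H))
  for (i in seq_len(nrow(H)))
    out[i, ] <- H[i, ] - log(sum(exp(H[i, ])))
  out
}

# Dense GAT forward by per-node enumeration of the attention mechanism.
oracle_gat_forward <- function(graph, X, params) {
  n <- graph$n
  nbrs <- lapply(seq_len(n), function(i) {
    e <- graph$edges
    sort(unique(c(i, e$j[e$i == i], e$i[e$j == i])))
  })
  lrelu <- function(x) if (x > 0) x else 0.2 * x
  H <- as.matrix(X)
  L <- length(params$layers)
  for (l in seq_len(L)) {
    heads <- params$layers[[l]]$heads
    outs <- lapply(heads, function(hd) {
      G <- H %*% hd$W
      O <- matrix(0, n, ncol(G))
      for (i in seq_len(n)) {
        js <- nbrs[[i]]
        e <- vapply(js, function(j)
          lrelu(sum(hd$a_src * G[i, ]) + sum(hd$a_dst * G[j, ])), numeric(1))
        a <- exp(e - max(e)); a <- a / sum(a)
        for (kk in seq_along(js)) O[i, ] <- O[i, ] + a[kk] * G[js[kk], ]
      }
      O
    })
    Z <- if (l < L) do.call(cbind, outs) else Reduce(`+`, outs) / length(outs)
    H <- if (l < L) ifelse(Z > 0, Z, 0) else Z
  }
  out <- matrix(NA_real_, n, ncol(H))
  for (i in seq_len(n)) out[i, ] <- H[i, ] - log(sum(exp(H[i, ])))
  out
}

# All-pairs AUC with ties counted one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Two-pass covariance / sd Pearson.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  cv <- sum((x - mx) * (y - my)) / n
  sx <- sqrt(sum((x - mx)^2) / n); sy <- sqrt(sum((y - my)^2) / n)
  cv / (sx * sy)
}

# Random undirected graph as a trial_graph (not via k-NN construction).
random_trial_graph <- function(n, p_edge = 0.4, weighted = FALSE) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (runif(1) < p_edge) A[i, j] <- A[j, i] <- if (weighted) runif(1) else 1
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  g <- structure(list(n = n,
                      edges = data.frame(i = idx[, 1], j = idx[, 2],
                                         weight = A[idx]),
                      A = Matrix::Matrix(A, sparse = TRUE), A_hat = NULL),
                 class = "trial_graph")
  normalize_adjacency(g)
}

# Central finite-difference gradient of an objective over a nested
# parameter list; returns the flat gradient vector.
fd_gradient <- function(obj_fn, params, h = 1e-5) {
  theta <- unlist(params, use.names = FALSE)
  g <- numeric(length(theta))
  for (k in seq_along(theta)) {
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    g[k] <- (obj_fn(cropgraph:::refill_params(tp, params)) -
             obj_fn(cropgraph:::refill_params(tm, params))) / (2 * h)
  }
  g
}

rel_err <- function(a, b) sqrt(sum((a - b)^2)) / max(1e-8, sqrt(sum(b^2)))
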