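# Record-to-record graph construction: chord-distance k-nearest-neighbour
# edges over direction-normalized feature rows, plus the renormalized
# propagation operator A_hat = D^(-1/2) (A + I) D^(-1/2).

#' Chord distance between two vectors
#'
#' Euclidean distance between the direction-normalized vectors u/||u|| and
#' v/||v||, i.e. sqrt(2 - 2 cos(theta)); range \[0, 2\], scale-invariant in
#' either argument.
#'
#' @param u,v Numeric vectors of equal length, both nonzero.
#' @return The chord distance.
#' @export
#' @examples
#' chord_distance(c(1, 0), c(0, 1))  # sqrt(2)
chord_distance <- function(u, v) {
  if (length(u) != length(v)) stop("length mismatch")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("chord distance undefined for a zero vector")
  cosuv <- sum(u * v) / (nu * nv)
  sqrt(max(0, 2 - 2 * cosuv))
}

#' Build a chord-distance k-nearest-neighbour trial graph
#'
#' Each record (node) selects its `k` nearest neighbours by chord distance
#' over its feature row; the edge set is the symmetrized union (an edge is
#' kept if either endpoint selects it). Distance ties are broken towards
#' the lower row index. Edge weights are 1 when `weighted = FALSE`,
#' otherwise the cosine similarity `1 - d^2/2` clipped to be non-negative.
#' The renormalized propagation operator is attached via
#' [normalize_adjacency()].
#'
#' @param features Numeric matrix (records x features), no zero rows.
#' @param k Neighbours per node, `1 <= k < n`.
#' @param weighted Use cosine-similarity edge weights (default `FALSE`).
#' @param block_size Rows per block in the blocked similarity computation.
#' @return A `trial_graph`: list with `n`, `edges` (data frame `i`, `j`,
#'   `weight`, `i < j`), sparse adjacency `A` and propagation operator
#'   `A_hat`.
#' @export
build_knn_graph <- function(features, k = 10, weighted = FALSE,
                            block_size = 1000L) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (k < 1 || k >= n) stop("require 1 <= k < n")
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) stop("zero feature row(s): direction undefined")
  U <- X / nrm

  nb <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block_size)) {
    idx <- start:min(start + block_size - 1L, n)
    S <- U[idx, , drop = FALSE] %*% t(U)     # cosine similarities
    for (r in seq_along(idx)) {
      i <- idx[r]
      s <- S[r, ]
      s[i] <- -Inf                           # no self-edge
      # largest cosine = smallest chord distance; order() is stable, so
      # ties fall to the lower row index
      nb[i, ] <- order(-s)[seq_len(k)]
    }
  }

  src <- rep(seq_len(n), k)
  dst <- as.vector(nb)
  ii <- pmin(src, dst); jj <- pmax(src, dst)
  keep <- !duplicated(cbind(ii, jj))
  ii <- ii[keep]; jj <- jj[keep]
  ord <- order(ii, jj)
  ii <- ii[ord]; jj <- jj[ord]

  w <- if (weighted) pmax(0, rowSums(U[ii, , drop = FALSE] * U[jj, , drop = FALSE]))
       else rep(1, length(ii))

  A <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(w, w),
                            dims = c(n, n))
  g <- structure(list(n = n, edges = data.frame(i = ii, j = jj, weight = w),
                      A = A, A_hat = NULL),
                 class = "trial_graph")
  normalize_adjacency(g)
}

#' Renormalized propagation operator of a trial graph
#'
#' Computes `A_hat = D^(-1/2) (A + I) D^(-1/2)` where `D` is the diagonal
#' of row sums of `A + I` (self-loops added). Isolated nodes get a unit
#' self-entry. The operator is symmetric and stored sparse.
#'
#' @param graph A `trial_graph` (field `A` assembled).
#' @return The graph with `A_hat` filled in.
#' @export
normalize_adjacency <- function(graph) {
  A_tilde <- graph$A + Matrix::Diagonal(graph$n)
  d <- Matrix::rowSums(A_tilde)
  Dinv <- Matrix::Diagonal(graph$n, 1 / sqrt(d))
  graph$A_hat <- to_dgc(Dinv %*% A_tilde %*% Dinv)
  graph
}

# Canonical general column-sparse form (the layout the compiled
# multiplication kernel consumes).
to_dgc <- function(A) {
  if (methods::is(A, "dgCMatrix")) return(A)
  methods::as(methods::as(methods::as(A, "CsparseMatrix"), "generalMatrix"),
              "dMatrix")
}

#' @export
print.trial_graph <- function(x, ...) {
  cat(sprintf("trial_graph: %d nodes, %d undirected edges (mean degree %.1f)\n",
              x$n, nrow(x$edges), 2 * nrow(x$edges) / x$n))
  invisible(x)
}

#' Write a trial graph edge list as TSV
#'
#' Columns `src`, `dst`, `weight`, tab-separated, one undirected edge per
#' line (`src < dst`).
#'
#' @param graph A `trial_graph`.
#' @param path Output file path.
#' @export
write_graph_tsv <- function(graph, path) {
  df <- graph$edges
  names(df) <- c("src", "dst", "weight")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
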