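test_that("attention forward matches the dense enumeration oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:10, 1)
    g <- random_trial_graph(n, p_edge = 0.5)
    X <- matrix(rnorm(n * 3), n)
    params <- gat_init(3, hidden = 4, heads = 2, seed = seed + 50)
    logp <- gat_forward(g, X, params)
    expect_equal(logp, oracle_gat_forward(g, X, params), tolerance = 1e-10)
    expect_equal(rowSums(exp(logp)), rep(1, n), tolerance = 1e-10)
  }
})

test_that("attention weights are a proper distribution over neighbourhoods", {
  set.seed(9)
  g <- random_trial_graph(7, p_edge = 0.5)
  X <- matrix(rnorm(21), 7)
  params <- gat_init(3, hidden = 4, heads = 2, seed = 3)
  fw <- cropgraph:::gat_forward_full(g, X, params)
  ei <- fw$ei
  for (hc in fw$caches[[1]]$heads) {
    sums <- rowsum(hc$alpha, ei$src)[, 1]
    expect_equal(unname(sums), rep(1, 7), tolerance = 1e-10)
  }
})

test_that("an isolated node attends only to itself", {
  g <- structure(list(n = 1, edges = data.frame(i = integer(0),
                                                j = integer(0),
                                                weight = numeric(0)),
                      A = Matrix::Matrix(0, 1, 1, sparse = TRUE),
                      A_hat = NULL),
                 class = "trial_graph")
  g <- normalize_adjacency(g)
  params <- gat_init(2, hidden = 4, heads = 2, seed = 1)
  fw <- cropgraph:::gat_forward_full(g, matrix(c(1, 2), 1), params)
  for (hc in fw$caches[[1]]$heads) expect_equal(hc$alpha, 1)
})

test_that("identical neighbour features receive uniform attention", {
  # a 4-clique where every node has the same feature vector
  A <- matrix(1, 4, 4); diag(A) <- 0
  idx <- which(upper.tri(A), arr.ind = TRUE)
  g <- structure(list(n = 4, edges = data.frame(i = idx[, 1], j = idx[, 2],
                                                weight = 1),
                      A = Matrix::Matrix(A, sparse = TRUE), A_hat = NULL),
                 class = "trial_graph")
  g <- normalize_adjacency(g)
  X <- matrix(rep(c(1, -2), each = 4), 4)
  params <- gat_init(2, hidden = 4, heads = 2, seed = 5)
  fw <- cropgraph:::gat_forward_full(g, X, params)
  for (hc in fw$caches[[1]]$heads)
    expect_equal(hc$alpha, rep(0.25, 16), tolerance = 1e-12)
})

test_that("attention gradients agree with central finite differences", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 5
    g <- random_trial_graph(n, p_edge = 0.6)
    X <- matrix(rnorm(n * 3), n)
    params <- gat_init(3, hidden = 4, heads = 2, seed = seed + 70)
    y <- sample(0:1, n, replace = TRUE)
    mask <- 1:3
    wd <- 0.01
    bw <- gat_backward(g, X, params, y, mask, wd)
    g_an <- unlist(bw$grads, use.names = FALSE)
    obj <- function(p) cropgraph:::gat_objective(g, X, p, y, mask, wd)
    g_fd <- fd_gradient(obj, params)
    expect_lt(rel_err(g_an, g_fd), 1e-4)
  }
})

test_that("gat training is deterministic and learns a separable toy graph", {
  n_half <- 5
  A <- matrix(0, 2 * n_half, 2 * n_half)
  A[1:n_half, 1:n_half] <- 1
  A[(n_half + 1):(2 * n_half), (n_half + 1):(2 * n_half)] <- 1
  diag(A) <- 0
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  g <- structure(list(n = 2 * n_half,
                      edges = data.frame(i = idx[, 1], j = idx[, 2],
                                         weight = 1),
                      A = Matrix::Matrix(A, sparse = TRUE), A_hat = NULL),
                 class = "trial_graph")
  g <- normalize_adjacency(g)
  set.seed(6)
  X <- cbind(rep(c(1, 0), each = n_half), rep(c(0, 1), each = n_half)) +
    matrix(rnorm(4 * n_half, sd = 0.1), 2 * n_half)
  y <- rep(c(0L, 1L), each = n_half)
  cfg <- train_config(budget = 2, hidden = 4, epochs = 150, seed = 2)
  f1 <- train_gat(g, X, y, c(1L, n_half + 1L), cfg)
  f2 <- train_gat(g, X, y, c(1L, n_half + 1L), cfg)
  expect_identical(f1$params, f2$params)
  pr <- predict_gat(f1$params, g, X)
  expect_identical(pr$label, y)
})
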