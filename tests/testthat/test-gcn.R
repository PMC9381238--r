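rand_instance <- function(n = 6, d = 3, h = 4, seed = 1, generic_bias = FALSE) {
  set.seed(seed)
  g <- random_trial_graph(n, p_edge = 0.5)
  X <- matrix(rnorm(n * d), n)
  params <- gcn_init(d, h, seed = seed + 100)
  if (generic_bias) {
    # keep pre-activations away from the exact ReLU kink so the objective
    # is differentiable at the test point
    params$b <- lapply(params$b, function(bb) runif(length(bb), 0.05, 0.15))
  }
  y <- sample(0:1, n, replace = TRUE)
  list(g = g, X = X, params = params, y = y)
}

test_that("forward pass matches the dense oracle and normalizes rows", {
  for (seed in 1:5) {
    inst <- rand_instance(n = sample(4:10, 1), seed = seed)
    logp <- gcn_forward(inst$g$A_hat, inst$X, inst$params)
    expect_equal(logp, oracle_gcn_forward(inst$g$A_hat, inst$X, inst$params),
                 tolerance = 1e-10)
    expect_equal(rowSums(exp(logp)), rep(1, nrow(inst$X)), tolerance = 1e-10)
  }
})

test_that("zero weights give the uniform binary prediction", {
  g <- random_trial_graph(1, p_edge = 0)
  params <- gcn_init(3, 4, seed = 1)
  params$W <- lapply(params$W, function(w) w * 0)
  logp <- gcn_forward(g$A_hat, matrix(rnorm(3), 1), params)
  expect_equal(drop(logp), c(log(0.5), log(0.5)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("nll_loss evaluates masked negative log likelihood", {
  lp <- matrix(log(0.5), 2, 2)
  expect_equal(nll_loss(lp, c(0L, 1L), 1:2), log(2), tolerance = 1e-12)
  perfect <- log(cbind(c(1, 1e-300), c(1e-300, 1)))
  expect_equal(nll_loss(perfect, c(0L, 1L), 1:2), 0, tolerance = 1e-12)
  lp2 <- log(rbind(c(0.8, 0.2), c(0.4, 0.6)))
  expect_equal(nll_loss(lp2, c(0L, 1L), 1:2), -(log(0.8) + log(0.6)) / 2,
               tolerance = 1e-12)
  expect_equal(nll_loss(lp2, c(0L, 1L), 1L), -log(0.8), tolerance = 1e-12)
  expect_error(nll_loss(lp2, c(0L, 1L), integer(0)), "empty mask")
})

test_that("backward gradients agree with central finite differences", {
  for (seed in 1:5) {
    inst <- rand_instance(n = 5, d = 3, h = 3, seed = seed + 20,
                          generic_bias = TRUE)
    mask <- which(seq_len(5) <= 3)
    wd <- 0.01
    bw <- gcn_backward(inst$g$A_hat, inst$X, inst$params, inst$y, mask, wd)
    g_an <- unlist(list(W = bw$W, b = bw$b), use.names = FALSE)
    obj <- function(p) cropgraph:::gcn_objective(inst$g$A_hat, inst$X, p,
                                                 inst$y, mask, wd)
    g_fd <- fd_gradient(obj, inst$params)
    expect_lt(rel_err(g_an, g_fd), 1e-4)
  }
})

test_that("the weight-decay term contributes exactly lambda * W", {
  inst <- rand_instance(seed = 31)
  mask <- 1:4
  g0 <- gcn_backward(inst$g$A_hat, inst$X, inst$params, inst$y, mask, 0.02)
  g1 <- gcn_backward(inst$g$A_hat, inst$X, inst$params, inst$y, mask, 0.04)
  for (l in 1:5) {
    expect_equal(g1$W[[l]] - g0$W[[l]], 0.02 * inst$params$W[[l]],
                 tolerance = 1e-12)
    expect_equal(g1$b[[l]], g0$b[[l]], tolerance = 1e-15)  # biases unpenalized
  }
})

test_that("adam behaves per its closed form on the first step", {
  cfg <- train_config(budget = 1, lr = 0.01, seed = 1)
  p <- list(x = 5)
  st <- adam_init(p)
  up <- adam_step(p, list(x = 0.3), st, cfg)
  # bias-corrected first step has magnitude ~ lr for |g| >> eps
  expect_equal(p$x - up$params$x, 0.01, tolerance = 1e-6)
  dn <- adam_step(p, list(x = -0.3), st, cfg)
  expect_equal(dn$params$x - p$x, 0.01, tolerance = 1e-6)  # opposite sign
  z <- adam_step(p, list(x = 0), adam_init(p), cfg)
  expect_equal(z$params$x, p$x)                            # zero gradient
  expect_identical(up$state$step, 1L)
})

test_that("a separable two-clique graph is learned to training accuracy 1", {
  n_half <- 6
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
  set.seed(4)
  X <- cbind(rep(c(1, 0), each = n_half), rep(c(0, 1), each = n_half)) +
    matrix(rnorm(4 * n_half, sd = 0.1), 2 * n_half)
  y <- rep(c(0L, 1L), each = n_half)
  cfg <- train_config(budget = 2, hidden = 8, epochs = 200, seed = 2)
  fit <- train_gcn(g, X, y, c(1L, n_half + 1L), cfg)
  pr <- predict_gcn(fit$params, g, X)
  expect_identical(pr$label, y)
  # loss is weakly decreasing over the last 50 epochs (1e-6 jitter allowed)
  tail50 <- tail(fit$loss_history, 50)
  expect_true(all(diff(tail50) <= 1e-6))
})

test_that("training is deterministic and validates the budget", {
  d <- quick_graph_data(n = 150, seed = 5)
  cfg <- train_config(budget = 30, hidden = 8, epochs = 10, seed = 3)
  mask <- which(seq_len(150) %% 5 == 0)
  f1 <- train_gcn(d$graph, d$X, d$tab$label, mask, cfg)
  f2 <- train_gcn(d$graph, d$X, d$tab$label, mask, cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_error(train_gcn(d$graph, d$X, d$tab$label, mask[-1], cfg), "budget")
})

test_that("predictions are permutation-consistent and tie to class 0", {
  inst <- rand_instance(n = 8, seed = 77)
  logp <- gcn_forward(inst$g$A_hat, inst$X, inst$params)
  perm <- sample(8)
  P <- as(as.integer(perm), "pMatrix")
  Ahat_p <- inst$g$A_hat[perm, perm]
  gp <- inst$g; gp$A_hat <- Ahat_p
  pr <- predict_gcn(inst$params, inst$g, inst$X)
  prp <- predict_gcn(inst$params, gp, inst$X[perm, ])
  expect_equal(prp$prob, pr$prob[perm], tolerance = 1e-12)
  expect_identical(prp$label, pr$label[perm])
  # exact ties resolve to the negative class
  zero <- gcn_init(3, 4, seed = 1)
  zero$W <- lapply(zero$W, function(w) w * 0)
  g1 <- random_trial_graph(1, p_edge = 0)
  tie <- predict_gcn(zero, g1, matrix(rnorm(3), 1))
  expect_identical(tie$label, 0L)
})
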