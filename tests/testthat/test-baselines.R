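sep_data <- function(n = 60, seed = 1) {
  # linearly separable two-class clouds in 2D
  set.seed(seed)
  X <- rbind(matrix(rnorm(n, mean = -2, sd = 0.4), n / 2),
             matrix(rnorm(n, mean = 2, sd = 0.4), n / 2))
  colnames(X) <- c("f1", "f2")
  list(X = X, y = rep(c(0L, 1L), each = n / 2))
}

test_that("nearest neighbour of a training point is itself", {
  X <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), 4, 2, byrow = TRUE)
  colnames(X) <- c("f1", "f2")
  y <- c(0L, 1L, 1L, 0L)
  m <- fit_baseline(baseline_spec("KNN", k = 1), X, y)
  pr <- predict_baseline(m, X)
  expect_identical(pr$label, y)
})

test_that("logistic regression separates a separable toy set", {
  d <- sep_data()
  m <- fit_baseline(baseline_spec("LR"), d$X, d$y)
  pr <- predict_baseline(m, d$X)
  expect_identical(pr$label, d$y)
  # scores are probabilities, monotone with the label rule
  expect_true(all(pr$score >= 0 & pr$score <= 1))
  expect_identical(pr$label, as.integer(pr$score > 0.5))
})

test_that("every tabular learner fits, predicts deterministically, and scores", {
  d <- quick_graph_data(n = 250, seed = 8)
  y <- d$tab$label
  tr <- 1:200; te <- 201:250
  for (name in c("KNN", "LR", "SVM", "NB", "DT", "RF", "MLP", "RBFNN")) {
    spec <- if (name == "MLP") baseline_spec("MLP", seed = 4, epochs = 30,
                                             hidden = 8)
            else baseline_spec(name, seed = 4)
    m <- fit_baseline(spec, d$X[tr, ], y[tr])
    p1 <- predict_baseline(m, d$X[te, ])
    p2 <- predict_baseline(m, d$X[te, ])
    expect_identical(p1, p2)
    expect_true(all(p1$label %in% c(0L, 1L)))
    expect_length(p1$score, length(te))
    expect_gt(suppressWarnings(auc(p1$score, y[te])), 0.5)
  }
  expect_error(fit_baseline(baseline_spec("LR"), d$X[tr, ], rep(1L, 200)),
               "single-class")
  expect_error(baseline_spec("XGB"))
  m <- fit_baseline(baseline_spec("RF", seed = 1), d$X[tr, ], y[tr])
  expect_error(predict_baseline(m, d$X[te, 1:10]), "columns")
})

test_that("a single unlimited tree and a one-tree forest agree when separable", {
  d <- sep_data(n = 80, seed = 3)
  dt <- fit_baseline(baseline_spec("DT", seed = 1), d$X, d$y)
  rf <- fit_baseline(baseline_spec("RF", seed = 1, ntree = 1), d$X, d$y)
  expect_identical(predict_baseline(dt, d$X)$label,
                   predict_baseline(rf, d$X)$label)
})

test_that("cross entropy follows its closed forms and clips degenerate q", {
  expect_equal(mlp_cross_entropy(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(mlp_cross_entropy(1, 0.8), -log(0.8), tolerance = 1e-12)
  expect_equal(mlp_cross_entropy(1, 1 - 1e-9), 0, tolerance = 1e-6)
  # p = q: cross entropy equals the entropy of p
  p <- 0.3
  expect_equal(mlp_cross_entropy(p, p), -(p * log(p) + (1 - p) * log(1 - p)),
               tolerance = 1e-12)
  expect_warning(h <- mlp_cross_entropy(1, 1), "clipped")
  expect_true(is.finite(h))
})

test_that("the RBF network interpolates with one centre per point", {
  set.seed(2)
  X <- matrix(rnorm(16), 8, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- c(0L, 1L, 1L, 0L, 1L, 0L, 0L, 1L)
  fit <- rbfnn_fit(X, y, n_centers = 8, seed = 1, lambda = 1e-10)
  pr <- cropgraph:::rbfnn_predict(fit, X)
  expect_equal(pr$score, y, tolerance = 1e-3, ignore_attr = TRUE)
  expect_identical(pr$label, y)
  # one-centre degenerate model still produces a monotone radial score
  fit1 <- rbfnn_fit(X, y, n_centers = 1, seed = 1)
  expect_length(cropgraph:::rbfnn_predict(fit1, X)$score, 8)
  # asking for more centres than distinct rows shrinks with a warning
  expect_warning(rbfnn_fit(X[c(1, 1, 2), ], c(0L, 0L, 1L), n_centers = 5,
                           seed = 1), "reduced")
})

test_that("the six-layer MLP drives training cross entropy down", {
  d <- sep_data(n = 40, seed = 5)
  m <- fit_baseline(baseline_spec("MLP", seed = 2, epochs = 100, hidden = 8),
                    d$X, d$y)
  pr <- predict_baseline(m, d$X)
  expect_identical(pr$label, d$y)
  q <- pmin(pmax(pr$score, 1e-12), 1 - 1e-12)
  expect_lt(mlp_cross_entropy(d$y, q) / length(d$y), log(2))
})
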