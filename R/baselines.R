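# Classical comparison classifiers behind a single fit/predict contract.
# Standard learners come from their established implementations
# (class::knn, stats::glm, e1071::svm / naiveBayes, rpart, randomForest);
# the six-layer MLP reuses the package's own dense layer stack and Adam
# (identity propagation instead of a graph), and the RBF network is
# k-means centres + regularized least squares. The graph models (GCN,
# GAT) live in their own modules and are trained transductively.

#' Baseline model specification
#'
#' @param name One of `"KNN"`, `"LR"`, `"SVM"`, `"NB"`, `"DT"`, `"RF"`,
#'   `"MLP"`, `"RBFNN"`.
#' @param seed Integer seed for stochastic learners.
#' @param ... Hyperparameter overrides: `k` (KNN neighbours, default 15),
#'   `cost` (SVM, default 1), `ntree` (RF, default 100), `hidden`/`lr`/
#'   `epochs`/`weight_decay` (MLP), `n_centers`/`lambda` (RBFNN).
#' @return A `baseline_spec`.
#' @export
baseline_spec <- function(name, seed = 1L, ...) {
  name <- match.arg(name, c("KNN", "LR", "SVM", "NB", "DT", "RF",
                            "MLP", "RBFNN"))
  defaults <- switch(name,
    KNN = list(k = 15),
    LR = list(),
    SVM = list(cost = 1),
    NB = list(),
    DT = list(),
    RF = list(ntree = 100),
    MLP = list(hidden = 64, lr = 0.01, epochs = 200, weight_decay = 5e-4),
    RBFNN = list(n_centers = 64, lambda = 1e-6))
  hp <- utils::modifyList(defaults, list(...))
  structure(list(name = name, hyper = hp, seed = as.integer(seed)),
            class = "baseline_spec")
}

#' Fit a baseline classifier
#'
#' @param spec A [baseline_spec()].
#' @param X_train Complete numeric matrix (rows x features).
#' @param y_train Integer 0/1 labels (both classes present).
#' @return A `baseline_model` ready for [predict_baseline()].
#' @export
fit_baseline <- function(spec, X_train, y_train) {
  stopifnot(inherits(spec, "baseline_spec"), !anyNA(X_train))
  if (length(unique(y_train)) < 2) stop("single-class training labels")
  yf <- factor(y_train, levels = c(0, 1))
  set.seed(spec$seed)
  hp <- spec$hyper
  fit <- switch(spec$name,
    KNN = list(X = X_train, y = yf, k = hp$k),   # lazy learner
    LR = {
      df <- data.frame(y = y_train, X_train, check.names = FALSE)
      suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    },
    SVM = e1071::svm(X_train, yf, kernel = "radial", cost = hp$cost,
                     scale = FALSE),
    NB = e1071::naiveBayes(X_train, yf),
    DT = {
      df <- data.frame(y = yf, X_train, check.names = FALSE)
      rpart::rpart(y ~ ., data = df, method = "class")
    },
    RF = randomForest::randomForest(X_train, yf, ntree = hp$ntree),
    MLP = mlp_fit(X_train, y_train, hidden = hp$hidden, lr = hp$lr,
                  epochs = hp$epochs, weight_decay = hp$weight_decay,
                  seed = spec$seed),
    RBFNN = rbfnn_fit(X_train, y_train, n_centers = hp$n_centers,
                      seed = spec$seed, lambda = hp$lambda))
  structure(list(spec = spec, fit = fit, columns = colnames(X_train)),
            class = "baseline_model")
}

#' Predict labels and positive-class scores from a fitted baseline
#'
#' Scores are class-1 probabilities where the learner provides them and
#' the (orientation-corrected) decision margin for the SVM; labels are
#' the 0.5-threshold / argmax rule.
#'
#' @param model A `baseline_model`.
#' @param X Numeric matrix with the training columns.
#' @return List with integer `label` and numeric `score`.
#' @export
predict_baseline <- function(model, X) {
  if (!identical(colnames(X), model$columns))
    stop("feature columns do not match the training columns")
  spec <- model$spec; fit <- model$fit
  out <- switch(spec$name,
    KNN = {
      set.seed(spec$seed)
      pr <- class::knn(fit$X, X, fit$y, k = fit$k, prob = TRUE)
      p_win <- attr(pr, "prob")
      score <- ifelse(pr == "1", p_win, 1 - p_win)
      list(label = as.integer(as.character(pr)), score = score)
    },
    LR = {
      p <- predict(fit, newdata = as.data.frame(X), type = "response")
      list(label = as.integer(p > 0.5), score = unname(p))
    },
    SVM = {
      pr <- predict(fit, X, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # orient the margin towards class "1"
      score <- if (grepl("^1/", colnames(dv)[1])) dv[, 1] else -dv[, 1]
      list(label = as.integer(as.character(pr)), score = unname(score))
    },
    NB = {
      p <- predict(fit, X, type = "raw")[, "1"]
      list(label = as.integer(p > 0.5), score = unname(p))
    },
    DT = {
      p <- predict(fit, as.data.frame(X), type = "prob")[, "1"]
      list(label = as.integer(p > 0.5), score = unname(p))
    },
    RF = {
      p <- predict(fit, X, type = "prob")[, "1"]
      list(label = as.integer(p > 0.5), score = unname(p))
    },
    MLP = mlp_predict(fit, X),
    RBFNN = rbfnn_predict(fit, X))
  out
}

# Cross entropy --------------------------------------------------------------

#' Binary cross entropy between an expected and a predicted distribution
#'
#' `H(p, q) = -sum(p log q + (1 - p) log(1 - q))` over the supplied
#' positive-class probabilities. Predicted components equal to 0 or 1 are
#' clipped at 1e-12 with a warning.
#'
#' @param p Expected positive-class probability (scalar or vector).
#' @param q Predicted positive-class probability, same length.
#' @return Scalar cross entropy (summed over elements).
#' @export
#' @examples
#' mlp_cross_entropy(1, 0.8)  # -log(0.8)
mlp_cross_entropy <- function(p, q) {
  stopifnot(length(p) == length(q), all(p >= 0 & p <= 1))
  if (any(q <= 0 | q >= 1)) {
    warning("predicted probabilities clipped to (1e-12, 1 - 1e-12)")
    q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
  }
  -sum(p * log(q) + (1 - p) * log(1 - q))
}

# Six-layer MLP ---------------------------------------------------------------

# The same five-matrix layer stack as the graph classifier with identity
# propagation; softmax cross entropy on one-hot targets coincides with
# the masked negative log-likelihood, so training reuses gcn_backward.
mlp_fit <- function(X, y, hidden = 64, lr = 0.01, epochs = 200,
                    weight_decay = 5e-4, seed = 1L) {
  n <- nrow(X)
  I_n <- Matrix::sparseMatrix(i = seq_len(n), j = seq_len(n), x = 1)
  cfg <- train_config(budget = n, hidden = hidden, lr = lr, epochs = epochs,
                      weight_decay = weight_decay, seed = seed)
  params <- gcn_init(ncol(X), hidden, seed = seed)
  state <- adam_init(params)
  for (ep in seq_len(epochs)) {
    g <- gcn_backward(I_n, X, params, y, seq_len(n), weight_decay, M1 = X)
    if (!is.finite(g$loss)) stop("MLP training diverged at epoch ", ep)
    upd <- adam_step(params, list(W = g$W, b = g$b), state, cfg)
    params <- upd$params; state <- upd$state
  }
  list(params = params)
}

mlp_predict <- function(fit, X) {
  n <- nrow(X)
  logp <- gcn_forward(Matrix::sparseMatrix(i = seq_len(n), j = seq_len(n),
                                           x = 1), X, fit$params)
  list(label = as.integer(logp[, 2] > logp[, 1]), score = exp(logp[, 2]))
}

# RBF network -----------------------------------------------------------------

#' Fit a radial basis function network
#'
#' Centres by seeded k-means, shared Gaussian width equal to the median
#' inter-centre distance, and a linear output layer fitted by regularized
#' least squares on the RBF features (intercept unpenalized).
#'
#' @param X_train Complete numeric matrix.
#' @param y_train Integer 0/1 labels.
#' @param n_centers Number of RBF centres (capped at the number of
#'   distinct training rows).
#' @param seed Integer seed for k-means.
#' @param lambda Ridge penalty on the output weights (default 1e-6).
#' @return An `rbfnn` model list.
#' @export
rbfnn_fit <- function(X_train, y_train, n_centers = 64, seed = 1L,
                      lambda = 1e-6) {
  Xu <- unique(X_train)
  if (n_centers > nrow(Xu)) {
    warning("n_centers reduced to the number of distinct rows (",
            nrow(Xu), ")")
    n_centers <- nrow(Xu)
  }
  set.seed(seed)
  centers <- if (n_centers == nrow(Xu)) Xu else
    kmeans(X_train, centers = n_centers, iter.max = 50, nstart = 1)$centers
  if (n_centers > 1) {
    dc <- as.matrix(stats::dist(centers))
    sigma <- median(dc[upper.tri(dc)])
    if (sigma == 0) sigma <- 1
  } else sigma <- 1
  Phi <- rbf_design(X_train, centers, sigma)
  A <- cbind(1, Phi)
  pen <- diag(c(0, rep(lambda, ncol(Phi))))
  beta <- solve(crossprod(A) + pen, crossprod(A, y_train))
  list(centers = as.matrix(centers), sigma = sigma, beta = drop(beta))
}

rbf_design <- function(X, centers, sigma) {
  d2 <- outer(rowSums(X^2), rowSums(centers^2), "+") -
    2 * X %*% t(centers)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

rbfnn_predict <- function(fit, X) {
  score <- drop(cbind(1, rbf_design(X, fit$centers, fit$sigma)) %*% fit$beta)
  list(label = as.integer(score > 0.5), score = score)
}
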