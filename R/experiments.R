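# End-to-end experiment suites: the label-budget accuracy grid across
# preprocessing modes, the ten-model five-metric comparison, and the
# paired relative-change-of-yield ablation. One synthetic dataset per
# suite; per-repeat seeds fan out deterministically from the master seed
# (split, budget draw and initialization all reseeded per repeat), so a
# manifest re-runs to bit-identical outputs.

#' Experiment configuration
#'
#' @param synth A [synthetic_config()] describing the dataset.
#' @param k Graph neighbours per node (default 10).
#' @param weighted Cosine edge weights (default FALSE).
#' @param modes Preprocessing modes for the budget grid.
#' @param budgets Label budgets (default `c(50, 100, 400, 700, 1000,
#'   2000)`); all must fit inside the training partition.
#' @param budget Label budget for the graph models in the comparison and
#'   ablation suites (default 1000).
#' @param models Models for the comparison/ablation suites.
#' @param train_frac Training partition fraction (default 0.8, i.e.
#'   8000:2000 at n = 10000).
#' @param n_reps Repeats to average (default 20).
#' @param hidden,epochs,lr,weight_decay Network training settings shared
#'   by GCN, GAT and the MLP.
#' @param z_threshold Outlier screening threshold (default 4).
#' @param tabular_train `"full"` (train tabular baselines on the whole
#'   training partition) or `"budget"` (on the same budgeted rows as the
#'   graph models).
#' @param out_dir Optional directory for CSV outputs and the manifest.
#' @param seed Master seed; repeat r uses `seed + r - 1`.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(synth = synthetic_config(),
                              k = 10, weighted = FALSE,
                              modes = c("raw", "standardized", "normalized"),
                              budgets = c(50, 100, 400, 700, 1000, 2000),
                              budget = 1000,
                              models = c("KNN", "LR", "SVM", "NB", "RF",
                                         "DT", "MLP", "RBFNN", "GAT", "GCN"),
                              train_frac = 0.8, n_reps = 20,
                              hidden = 64, epochs = 200, lr = 0.01,
                              weight_decay = 5e-4, z_threshold = 4,
                              tabular_train = c("full", "budget"),
                              out_dir = NULL, seed = 1L) {
  tabular_train <- match.arg(tabular_train)
  n_train <- round(train_frac * synth$n_records)
  if (max(budgets) > n_train || budget > n_train)
    stop("label budgets must not exceed the training partition size (",
         n_train, ")")
  structure(list(synth = synth, k = k, weighted = weighted, modes = modes,
                 budgets = budgets, budget = budget, models = models,
                 train_frac = train_frac, n_reps = as.integer(n_reps),
                 hidden = hidden, epochs = epochs, lr = lr,
                 weight_decay = weight_decay, z_threshold = z_threshold,
                 tabular_train = tabular_train, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# Deterministic train/test split and class-stratified budget draw -------------

split_train_test <- function(n, train_frac, seed) {
  set.seed(seed)
  train <- sort(sample.int(n, round(train_frac * n)))
  list(train = train, test = setdiff(seq_len(n), train))
}

draw_budget <- function(labels, train_idx, budget, seed) {
  stopifnot(budget <= length(train_idx))
  set.seed(seed)
  pos <- train_idx[labels[train_idx] == 1]
  neg <- train_idx[labels[train_idx] == 0]
  n1 <- round(budget * length(pos) / length(train_idx))
  n1 <- min(max(n1, 1), length(pos), budget - 1)
  sort(c(sample(pos, n1), sample(neg, budget - n1)))
}

binary_metrics <- function(pred, score, truth) {
  m <- metrics_from_confusion(confusion_counts(pred, truth))
  c(m, auc = auc(score, truth))
}

# One transductive graph-model run evaluated on the test partition.
run_graph_model <- function(name, graph, X, labels, budget_idx, test_idx,
                            cfg, seed) {
  tc <- train_config(budget = length(budget_idx), hidden = cfg$hidden,
                     lr = cfg$lr, epochs = cfg$epochs,
                     weight_decay = cfg$weight_decay, seed = seed)
  fit <- if (name == "GCN") train_gcn(graph, X, labels, budget_idx, tc)
         else train_gat(graph, X, labels, budget_idx, tc)
  pr <- if (name == "GCN") predict_gcn(fit$params, graph, X)
        else predict_gat(fit$params, graph, X)
  binary_metrics(pr$label[test_idx], pr$prob[test_idx], labels[test_idx])
}

run_tabular_model <- function(name, X, labels, fit_idx, test_idx, seed,
                              cfg = NULL) {
  spec <- if (name == "MLP" && !is.null(cfg))
    baseline_spec("MLP", seed = seed, hidden = cfg$hidden, lr = cfg$lr,
                  epochs = cfg$epochs, weight_decay = cfg$weight_decay)
  else baseline_spec(name, seed = seed)
  model <- fit_baseline(spec, X[fit_idx, , drop = FALSE], labels[fit_idx])
  pr <- predict_baseline(model, X[test_idx, , drop = FALSE])
  binary_metrics(pr$label, pr$score, labels[test_idx])
}

# Suite 1: budget grid over preprocessing modes -------------------------------

#' Label-budget accuracy grid of the graph classifier
#'
#' Trains the graph convolutional classifier at every label budget under
#' each preprocessing mode (raw / standardized / normalized) on one
#' synthetic dataset, averaging test-partition accuracy over
#' `config$n_reps` paired repeats.
#'
#' @param config An [experiment_config()].
#' @return List with `grid` (mode x budget mean/sd accuracy), `per_rep`,
#'   and `manifest`. If `config$out_dir` is set, writes
#'   `table1_grid.csv`, `table1_per_rep.csv` and `manifest_table1.json`.
#' @export
run_table1 <- function(config) {
  tab <- generate_trial_table(config$synth)
  n <- nrow(tab)
  rows <- list()
  for (mode in config$modes) {
    tm <- preprocess_mode(tab, mode, config$z_threshold)
    X <- feature_matrix(tm)
    graph <- build_knn_graph(X, config$k, config$weighted)
    for (r in seq_len(config$n_reps)) {
      seed_r <- config$seed + r - 1L
      sp <- split_train_test(n, config$train_frac, seed_r)
      for (bi in seq_along(config$budgets)) {
        b <- config$budgets[bi]
        bidx <- draw_budget(tab$label, sp$train, b, seed_r + 7919L * bi)
        met <- run_graph_model("GCN", graph, X, tab$label, bidx, sp$test,
                               config, seed_r)
        rows[[length(rows) + 1L]] <-
          data.frame(mode = mode, budget = b, rep = r, seed = seed_r,
                     accuracy = unname(met["accuracy"]))
      }
    }
  }
  per_rep <- do.call(rbind, rows)
  grid <- aggregate(accuracy ~ mode + budget, per_rep,
                    function(x) c(mean = mean(x), sd = sd(x)))
  grid <- data.frame(mode = grid$mode, budget = grid$budget,
                     mean_accuracy = grid$accuracy[, "mean"],
                     sd_accuracy = grid$accuracy[, "sd"])
  grid <- grid[order(match(grid$mode, config$modes), grid$budget), ]
  rownames(grid) <- NULL
  res <- list(grid = grid, per_rep = per_rep,
              manifest = manifest(config, "table1"))
  if (!is.null(config$out_dir)) {
    wide <- reshape_grid(grid, config$modes, config$budgets)
    write_outputs(config$out_dir, "table1",
                  list(grid = wide, per_rep = per_rep), res$manifest)
  }
  res
}

reshape_grid <- function(grid, modes, budgets) {
  wide <- data.frame(mode = modes)
  for (b in budgets)
    wide[[as.character(b)]] <-
      grid$mean_accuracy[match(paste(modes, b),
                               paste(grid$mode, grid$budget))]
  wide
}

# Suite 2: ten-model five-metric comparison ------------------------------------

#' Model comparison under the five-metric repeated protocol
#'
#' Runs every configured model on one standardized synthetic dataset:
#' graph models transductively at `config$budget` labelled nodes, tabular
#' baselines on the full training partition (or the same budgeted rows
#' when `config$tabular_train = "budget"`), all evaluated on the held-out
#' test partition and averaged over paired repeats.
#'
#' @param config An [experiment_config()].
#' @param tab Optional pre-generated `trial_table` (internal reuse).
#' @return List with `summary` (model x metric mean/sd), `per_rep`,
#'   `manifest`; CSVs written when `config$out_dir` is set.
#' @export
run_table2 <- function(config, tab = NULL) {
  if (is.null(tab)) tab <- generate_trial_table(config$synth)
  n <- nrow(tab)
  tm <- preprocess_mode(tab, "standardized", config$z_threshold)
  X <- feature_matrix(tm)
  graph_models <- intersect(config$models, c("GCN", "GAT"))
  graph <- if (length(graph_models))
    build_knn_graph(X, config$k, config$weighted) else NULL
  rows <- list()
  for (r in seq_len(config$n_reps)) {
    seed_r <- config$seed + r - 1L
    sp <- split_train_test(n, config$train_frac, seed_r)
    bidx <- draw_budget(tab$label, sp$train, config$budget, seed_r + 7919L)
    for (mod in config$models) {
      met <- if (mod %in% c("GCN", "GAT"))
        run_graph_model(mod, graph, X, tab$label, bidx, sp$test,
                        config, seed_r)
      else run_tabular_model(mod, X, tab$label,
                             if (config$tabular_train == "budget") bidx
                             else sp$train,
                             sp$test, seed_r, config)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(model = mod, rep = r, seed = seed_r),
              as.data.frame(as.list(met)))
    }
  }
  per_rep <- do.call(rbind, rows)
  metric_names <- c("accuracy", "precision", "recall", "f1", "auc")
  summary <- do.call(rbind, lapply(config$models, function(mod) {
    sub <- per_rep[per_rep$model == mod, metric_names]
    data.frame(model = mod, metric = metric_names,
               mean = colMeans(sub), sd = apply(sub, 2, sd),
               row.names = NULL)
  }))
  res <- list(summary = summary, per_rep = per_rep,
              manifest = manifest(config, "table2"))
  if (!is.null(config$out_dir)) {
    wide <- data.frame(metric = metric_names)
    for (mod in config$models)
      wide[[mod]] <- summary$mean[summary$model == mod]
    write_outputs(config$out_dir, "table2",
                  list(summary = wide, per_rep = per_rep), res$manifest)
  }
  res
}

# Suite 3: paired feature ablation ---------------------------------------------

#' Relative-change-of-yield ablation experiment
#'
#' Runs the model-comparison suite twice with identical per-repeat seeds:
#' once on all features and once with the `feature` column removed before
#' preprocessing and graph construction, so the accuracy change is paired
#' by seed.
#'
#' @param config An [experiment_config()].
#' @param feature Feature to ablate (default `"RCY"`).
#' @return List with `summary` (condition x model accuracy and the other
#'   metrics), `per_rep`, `manifest`; CSVs written when `config$out_dir`
#'   is set.
#' @export
run_table4 <- function(config, feature = "RCY") {
  tab <- generate_trial_table(config$synth)
  sub_cfg <- config
  sub_cfg$out_dir <- NULL
  all_res <- run_table2(sub_cfg, tab = tab)
  abl_res <- run_table2(sub_cfg, tab = ablate_feature(tab, feature))
  per_rep <- rbind(cbind(condition = "All data", all_res$per_rep),
                   cbind(condition = paste("No", feature), abl_res$per_rep))
  summary <- rbind(cbind(condition = "All data", all_res$summary),
                   cbind(condition = paste("No", feature), abl_res$summary))
  res <- list(summary = summary, per_rep = per_rep,
              manifest = manifest(config, "table4"))
  if (!is.null(config$out_dir)) {
    acc <- summary[summary$metric == "accuracy", ]
    wide <- data.frame(condition = unique(acc$condition))
    for (mod in config$models)
      wide[[mod]] <- acc$mean[match(paste(wide$condition, mod),
                                    paste(acc$condition, acc$model))]
    write_outputs(config$out_dir, "table4",
                  list(summary = wide, per_rep = per_rep), res$manifest)
  }
  res
}

# Manifest and outputs ---------------------------------------------------------

# Polynomial rolling hash mod 2^31 - 1; cheap content fingerprint for
# manifests (not cryptographic).
string_hash <- function(s) {
  bytes <- as.numeric(charToRaw(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

config_json <- function(config) {
  cfg <- unclass(config)
  cfg$synth <- unclass(cfg$synth)
  cfg$out_dir <- NULL
  jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
}

#' Experiment manifest
#'
#' Captures the full configuration, the per-repeat seeds, the package
#' version and a content hash of the configuration; re-running a suite
#' from the same manifest reproduces its CSV outputs bit-identically.
#'
#' @param config An [experiment_config()].
#' @param suite Suite label (`"table1"`, `"table2"`, `"table4"`).
#' @return A `manifest` list.
#' @export
manifest <- function(config, suite) {
  cj <- as.character(config_json(config))
  structure(list(suite = suite, config = config,
                 seeds = config$seed + seq_len(config$n_reps) - 1L,
                 package_version = as.character(utils::packageVersion("cropgraph")),
                 config_hash = string_hash(cj)),
            class = "manifest")
}

write_outputs <- function(out_dir, prefix, tables, man) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables))
    write.csv(tables[[nm]], file.path(out_dir, paste0(prefix, "_", nm, ".csv")),
              row.names = FALSE)
  man_out <- list(suite = man$suite,
                  config = jsonlite::fromJSON(as.character(config_json(man$config))),
                  seeds = man$seeds, package_version = man$package_version,
                  config_hash = man$config_hash)
  jsonlite::write_json(man_out, file.path(out_dir, paste0("manifest_", prefix, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Re-run a suite from its manifest
#'
#' @param man A `manifest` (as returned inside a suite result).
#' @param out_dir Directory for the reproduced outputs.
#' @return The suite result.
#' @export
rerun_manifest <- function(man, out_dir) {
  cfg <- man$config
  cfg$out_dir <- out_dir
  switch(man$suite,
         table1 = run_table1(cfg),
         table2 = run_table2(cfg),
         table4 = run_table4(cfg),
         stop("unknown suite: ", man$suite))
}
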