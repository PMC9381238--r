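# Small fixtures built in code.

small_config <- function(n = 400, seed = 1L, ...) {
  synthetic_config(n_records = n, seed = seed, ...)
}

# A clean (artifact-free) small table.
clean_table <- function(n = 400, seed = 1L, ...) {
  generate_trial_table(small_config(n, seed, outlier_rate = 0,
                                    missing_rate = 0, ...))
}

# Standardized features + graph for quick model runs.
quick_graph_data <- function(n = 300, seed = 1L, k = 8) {
  tab <- clean_table(n, seed)
  std <- standardize(tab)
  X <- feature_matrix(std)
  list(tab = tab, X = X, graph = build_knn_graph(X, k = k))
}
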