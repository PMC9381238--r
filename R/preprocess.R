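# Outlier screening with mean imputation, z-score standardization and
# min-max normalization. All column statistics use the population (n)
# denominator, computed over `stats_rows` (default: all rows, the
# transductive convention; pass the training rows for leak-free inductive
# baselines).

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Screen outliers and impute missing cells
#'
#' Automates manual outlier filtering as a per-column z-score rule: any
#' observed cell with |value - mean| / sd > `z_threshold` (mean and sd over
#' the observed cells of that column) is marked missing; every missing
#' cell — pre-existing or newly flagged — is then replaced by the column
#' mean over the remaining observed cells. The output has no missing cells.
#'
#' @param tab A `trial_table` (may contain `NA` cells).
#' @param z_threshold Positive z-score cut-off; default 4.
#' @return List with `table` (clean `trial_table`) and `report`
#'   (`preprocess_report`: per-column `n_outliers`, `n_imputed`, the
#'   `location`/`scale` statistics used, and `mode = "raw"`).
#' @export
screen_outliers <- function(tab, z_threshold = 4) {
  stopifnot(z_threshold > 0)
  X <- feature_matrix(tab)
  n_out <- n_imp <- integer(ncol(X))
  loc <- scl <- numeric(ncol(X))
  names(n_out) <- names(n_imp) <- names(loc) <- names(scl) <- colnames(X)
  for (j in seq_len(ncol(X))) {
    obs <- !is.na(X[, j])
    m <- mean(X[obs, j]); s <- pop_sd(X[obs, j])
    loc[j] <- m; scl[j] <- s
    if (s == 0) {
      if (any(!obs)) {
        warning("zero-variance column ", colnames(X)[j],
                ": imputing with its constant value")
        X[!obs, j] <- m
        n_imp[j] <- sum(!obs)
      }
      next
    }
    flag <- obs & abs(X[, j] - m) / s > z_threshold
    n_out[j] <- sum(flag)
    X[flag, j] <- NA_real_
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mean(X[!miss, j])
    n_imp[j] <- sum(miss)
  }
  report <- structure(list(n_outliers = n_out, n_imputed = n_imp,
                           location = loc, scale = scl,
                           z_threshold = z_threshold, mode = "raw"),
                      class = "preprocess_report")
  list(table = set_features(tab, X), report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("preprocess_report (mode %s): %d outlier cells flagged, %d cells imputed\n",
              x$mode, sum(x$n_outliers), sum(x$n_imputed)))
  invisible(x)
}

#' Standardize feature columns (z-score)
#'
#' Transforms each feature column to `(x - mean)/sd`, statistics computed
#' over `stats_rows` with the population (n) denominator. Zero-variance
#' columns are centred and left at scale 1, with a warning.
#'
#' @param tab A complete `trial_table` (no missing cells).
#' @param stats_rows Integer/logical row index over which to compute the
#'   statistics; default all rows.
#' @return The standardized `trial_table`.
#' @export
standardize <- function(tab, stats_rows = NULL) {
  X <- feature_matrix(tab)
  if (anyNA(X)) stop("standardize requires a complete table; run screen_outliers first")
  rows <- if (is.null(stats_rows)) seq_len(nrow(X)) else stats_rows
  m <- colMeans(X[rows, , drop = FALSE])
  s <- apply(X[rows, , drop = FALSE], 2, pop_sd)
  if (any(s == 0)) {
    warning("zero-variance column(s) left at scale 1: ",
            paste(colnames(X)[s == 0], collapse = ", "))
    s[s == 0] <- 1
  }
  set_features(tab, sweep(sweep(X, 2, m, "-"), 2, s, "/"))
}

#' Min-max normalize feature columns to \[0, 1\]
#'
#' Maps each feature column to `(x - min)/(max - min)`, the range taken
#' over `stats_rows`. Constant columns map to 0.5 everywhere, with a
#' warning.
#'
#' @inheritParams standardize
#' @return The normalized `trial_table`.
#' @export
normalize_minmax <- function(tab, stats_rows = NULL) {
  X <- feature_matrix(tab)
  if (anyNA(X)) stop("normalize_minmax requires a complete table; run screen_outliers first")
  rows <- if (is.null(stats_rows)) seq_len(nrow(X)) else stats_rows
  lo <- apply(X[rows, , drop = FALSE], 2, min)
  hi <- apply(X[rows, , drop = FALSE], 2, max)
  rng <- hi - lo
  const <- rng == 0
  if (any(const))
    warning("constant column(s) mapped to 0.5: ",
            paste(colnames(X)[const], collapse = ", "))
  rng[const] <- 1
  Y <- sweep(sweep(X, 2, lo, "-"), 2, rng, "/")
  Y[, const] <- 0.5
  set_features(tab, Y)
}

#' Apply a named preprocessing mode
#'
#' Convenience wrapper used by the experiment harnesses: screens outliers
#' (threshold `z_threshold`) then applies `"raw"` (no rescaling),
#' `"standardized"` or `"normalized"` scaling.
#'
#' @param tab A `trial_table`.
#' @param mode One of `"raw"`, `"standardized"`, `"normalized"`.
#' @param z_threshold Outlier screening threshold (default 4).
#' @param stats_rows Rows over which scaling statistics are computed
#'   (default all: transductive convention).
#' @return A complete, scaled `trial_table`.
#' @export
preprocess_mode <- function(tab, mode = c("standardized", "raw", "normalized"),
                            z_threshold = 4, stats_rows = NULL) {
  mode <- match.arg(mode)
  clean <- screen_outliers(tab, z_threshold)$table
  switch(mode,
         raw = clean,
         standardized = standardize(clean, stats_rows),
         normalized = normalize_minmax(clean, stats_rows))
}
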