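# Five-metric evaluation (accuracy, precision, recall, F1, AUC) with the
# 20-repeat averaging protocol and feature ablation. Positive class =
# "continuing test" (label 1).

#' Confusion counts of a binary prediction
#'
#' @param pred Integer 0/1 predictions.
#' @param truth Integer 0/1 reference labels.
#' @return A `confusion_counts` list with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  structure(list(TP = sum(pred == 1 & truth == 1),
                 FP = sum(pred == 1 & truth == 0),
                 FN = sum(pred == 0 & truth == 1),
                 TN = sum(pred == 0 & truth == 0)),
            class = "confusion_counts")
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' `accuracy = (TP+TN)/total`, `precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)`, `F1 = 2PR/(P+R)`. Undefined ratios (empty
#' denominator) are reported as 0 and flagged in the `undefined`
#' attribute, keeping aggregate runs deterministic.
#'
#' @param c A `confusion_counts` (total > 0).
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`.
#' @export
metrics_from_confusion <- function(c) {
  total <- c$TP + c$FP + c$FN + c$TN
  if (total == 0) stop("empty confusion counts")
  undef <- character(0)
  precision <- if (c$TP + c$FP == 0) { undef <- c(undef, "precision"); 0 }
               else c$TP / (c$TP + c$FP)
  recall <- if (c$TP + c$FN == 0) { undef <- c(undef, "recall"); 0 }
            else c$TP / (c$TP + c$FN)
  f1 <- if (precision + recall == 0) { undef <- c(undef, "f1"); 0 }
        else 2 * precision * recall / (precision + recall)
  out <- c(accuracy = (c$TP + c$TN) / total, precision = precision,
           recall = recall, f1 = f1)
  attr(out, "undefined") <- undef
  out
}

#' Rank-based AUC
#'
#' The probability that a random positive outscores a random negative
#' (ties counted 1/2), computed from midranks; identical to the
#' trapezoidal area under the ROC curve.
#'
#' @param scores Real-valued classifier scores (higher = more positive).
#' @param labels Integer 0/1 labels, both classes present.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("AUC undefined: single-class labels")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Repeat an experiment over consecutive seeds and aggregate
#'
#' Runs `run_fn(seed)` for seeds `base_seed .. base_seed + n_reps - 1`
#' (fresh splits/initializations are the run function's responsibility)
#' and aggregates each returned metric's mean and standard deviation.
#' Any failing repeat aborts with its seed.
#'
#' @param run_fn Function of one integer seed returning a named numeric
#'   vector of metrics.
#' @param n_reps Number of repeats (default 20).
#' @param base_seed First seed (default 1).
#' @return An `eval_report`: list with `mean`, `sd` (named vectors),
#'   `per_rep` (data frame, one row per repeat), `seeds`.
#' @export
repeated_eval <- function(run_fn, n_reps = 20, base_seed = 1L) {
  stopifnot(n_reps >= 1)
  seeds <- as.integer(base_seed) + seq_len(n_reps) - 1L
  rows <- lapply(seeds, function(s) {
    res <- tryCatch(run_fn(s),
                    error = function(e) stop("repeat with seed ", s,
                                             " failed: ", conditionMessage(e)))
    as.data.frame(as.list(res))
  })
  per_rep <- do.call(rbind, rows)
  structure(list(mean = colMeans(per_rep),
                 sd = apply(per_rep, 2, sd),
                 per_rep = cbind(seed = seeds, per_rep),
                 seeds = seeds),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report over %d repeats (seeds %d..%d):\n",
              length(x$seeds), min(x$seeds), max(x$seeds)))
  print(round(rbind(mean = x$mean, sd = x$sd), 4))
  invisible(x)
}

#' Drop one feature column from a trial table
#'
#' Used for the relative-change-of-yield ablation: the named feature is
#' removed, all other columns keep their order, and downstream graphs are
#' rebuilt from the reduced features.
#'
#' @param tab A `trial_table`.
#' @param feature_name Feature column to drop (e.g. `"RCY"`).
#' @return The reduced `trial_table`.
#' @export
ablate_feature <- function(tab, feature_name) {
  fn <- setdiff(names(tab), c("site_id", "label"))
  if (!feature_name %in% fn) stop("unknown feature: ", feature_name)
  out <- tab[, setdiff(names(tab), feature_name), drop = FALSE]
  for (a in c("config", "injected_outliers", "injected_missing"))
    attr(out, a) <- attr(tab, a)
  class(out) <- class(tab)
  out
}
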