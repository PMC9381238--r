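test_that("confusion metrics follow their closed forms", {
  m <- metrics_from_confusion(confusion_counts(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
                                               c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)))
  expect_equal(unname(m["accuracy"]), 0.8)
  expect_equal(unname(m["precision"]), 0.75)
  expect_equal(unname(m["recall"]), 0.75)
  expect_equal(unname(m["f1"]), 0.75)
  allc <- metrics_from_confusion(structure(list(TP = 4, FP = 0, FN = 0, TN = 6),
                                           class = "confusion_counts"))
  expect_equal(unname(allc), rep(1, 4), ignore_attr = TRUE)
})

test_that("the published precision/recall pair reproduces its F1", {
  # internal consistency of the harmonic-mean formula at P=0.687, R=0.911
  p <- 0.687; r <- 0.911
  f1 <- 2 * p * r / (p + r)
  expect_equal(round(f1, 3), 0.783)
  c0 <- structure(list(TP = 687, FP = 313, FN = round(687 / 0.911) - 687,
                       TN = 0), class = "confusion_counts")
  m <- metrics_from_confusion(c0)
  expect_equal(unname(m["precision"]), 0.687, tolerance = 1e-3)
  expect_equal(unname(m["recall"]), 0.911, tolerance = 1e-3)
  expect_equal(unname(round(m["f1"], 3)), 0.783, tolerance = 2e-3)
})

test_that("undefined ratios report zero and are flagged", {
  m <- metrics_from_confusion(structure(list(TP = 0, FP = 0, FN = 2, TN = 3),
                                        class = "confusion_counts"))
  expect_equal(unname(m["precision"]), 0)
  expect_setequal(attr(m, "undefined"), c("precision", "f1"))
  expect_error(metrics_from_confusion(structure(list(TP = 0, FP = 0, FN = 0,
                                                     TN = 0),
                                               class = "confusion_counts")),
               "empty")
})

test_that("F1 lies between precision and recall when both are defined", {
  set.seed(8)
  for (i in 1:50) {
    cc <- structure(as.list(rmultinom(1, 40, rep(0.25, 4))[, 1] + 1),
                    class = "confusion_counts")
    names(cc) <- c("TP", "FP", "FN", "TN")
    m <- metrics_from_confusion(cc)
    expect_lte(m[["f1"]], max(m[["precision"]], m[["recall"]]) + 1e-12)
    expect_gte(m[["f1"]], min(m[["precision"]], m[["recall"]]) - 1e-12)
  }
})

test_that("rank AUC matches enumeration, trapezoid and known cases", {
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)         # separating
  expect_equal(auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)    # uninformative
  set.seed(21)
  for (i in 1:20) {
    n <- sample(8:40, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(auc(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(auc(1:3, c(1, 1, 1)), "single-class")
})

test_that("rank AUC agrees with an established ROC implementation", {
  set.seed(33)
  scores <- rnorm(200)
  labels <- rbinom(200, 1, 0.4)
  expect_equal(auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("repeated evaluation aggregates over consecutive seeds", {
  run_fn <- function(seed) c(metric = seed * 2, fixed = 7)
  r1 <- repeated_eval(run_fn, n_reps = 1, base_seed = 5)
  expect_equal(unname(r1$mean["metric"]), 10)
  r <- repeated_eval(run_fn, n_reps = 4, base_seed = 3)
  expect_identical(r$seeds, 3:6)
  expect_equal(unname(r$mean["metric"]), mean(c(6, 8, 10, 12)))
  expect_equal(unname(r$sd["fixed"]), 0)
  r2 <- repeated_eval(run_fn, n_reps = 4, base_seed = 3)
  expect_identical(r$per_rep, r2$per_rep)
  bad <- function(seed) if (seed == 4) stop("boom") else c(m = 1)
  expect_error(repeated_eval(bad, n_reps = 3, base_seed = 3), "seed 4")
})

test_that("feature ablation drops exactly one column and round-trips", {
  tab <- clean_table(120, seed = 3)
  abl <- ablate_feature(tab, "RCY")
  expect_identical(ncol(feature_matrix(abl)), 38L)
  expect_false("RCY" %in% names(abl))
  expect_identical(setdiff(trial_feature_names(), "RCY"),
                   colnames(feature_matrix(abl)))
  back <- abl
  back$RCY <- tab$RCY
  back <- back[, names(tab)]
  expect_equal(feature_matrix(back), feature_matrix(tab), tolerance = 1e-15)
  expect_identical(back$label, tab$label)
  expect_error(ablate_feature(tab, "YIELD"), "unknown feature")
})
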