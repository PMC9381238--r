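#' @importFrom stats cor dnorm kmeans pnorm predict qnorm rnorm runif sd var median glm binomial aggregate dist
#' @importFrom utils write.csv read.csv write.table head modifyList packageVersion
NULL

# Canonical column vocabulary ------------------------------------------------

#' Canonical feature names of a variety-trial table
#'
#' The 39 per-record features used throughout the package: 15 phenotypic
#' traits (leaf blight LB, lodging rate LR, inversion rate IR, grey speck
#' disease GSD, plant height PH, ear height EH, empty stalk rate ESR,
#' duration period DP, ear rot ER, hundred-grain weight HGW, ear length EL,
#' bald tip length BTL, fresh ear field FEF, corn acre yield CAY, relative
#' change of yield RCY) followed by the growth-period mean ("A" prefix) and
#' variance ("V" prefix) of 12 climate variables (MaxT, AT, MinT, TD, GP,
#' RH, P, MWS, AWS, WDA, ST, WL).
#'
#' @return Character vector of length 39, in canonical column order.
#' @export
#' @examples
#' trial_feature_names()[1:5]
trial_feature_names <- function() {
  traits <- c("LB", "LR", "IR", "GSD", "PH", "EH", "ESR", "DP", "ER",
              "HGW", "EL", "BTL", "FEF", "CAY", "RCY")
  clim <- c("MaxT", "AT", "MinT", "TD", "GP", "RH", "P", "MWS", "AWS",
            "WDA", "ST", "WL")
  c(traits, as.vector(rbind(paste0("A", clim), paste0("V", clim))))
}

#' Names of the 15 phenotypic trait columns
#' @return Character vector of length 15.
#' @export
trait_feature_names <- function() trial_feature_names()[1:15]

#' Names of the 24 growth-period climate summary columns
#' @return Character vector of length 24.
#' @export
climate_feature_names <- function() trial_feature_names()[16:39]

# Constructor / validator ----------------------------------------------------

#' Construct a trial table
#'
#' A trial table is a data frame with one row per variety-by-site trial
#' record: a `site_id` factor, a binary `label` (1 = "continuing test",
#' the positive class; 0 = "termination test"), and numeric feature columns
#' (the canonical 39, or 38 after ablation). Missing cells are `NA`.
#'
#' @param site_id Factor or character vector of trial-site identifiers.
#' @param label Integer vector of 0/1 expert labels.
#' @param features Numeric matrix or data frame, one column per feature.
#' @return A `trial_table` (data frame subclass).
#' @export
trial_table <- function(site_id, label, features) {
  features <- as.data.frame(features)
  stopifnot(length(site_id) == nrow(features),
            length(label) == nrow(features))
  if (!all(label %in% c(0L, 1L)))
    stop("labels must be 0 (termination test) or 1 (continuing test)")
  tab <- data.frame(site_id = factor(site_id), label = as.integer(label),
                    features, check.names = FALSE)
  class(tab) <- c("trial_table", "data.frame")
  validate_trial_table(tab)
  tab
}

validate_trial_table <- function(tab) {
  fn <- setdiff(names(tab), c("site_id", "label"))
  if (length(fn) == 39L && !identical(fn, trial_feature_names()))
    stop("feature columns present but not in canonical order")
  vcols <- intersect(fn, grep("^V", climate_feature_names(), value = TRUE))
  for (v in vcols) {
    x <- tab[[v]]
    if (any(x < 0, na.rm = TRUE))
      stop("variance-type climate column ", v, " has negative observed values")
  }
  invisible(tab)
}

#' Extract the feature matrix of a trial table
#'
#' @param tab A `trial_table`.
#' @return Numeric matrix (records x features) with column names.
#' @export
feature_matrix <- function(tab) {
  fn <- setdiff(names(tab), c("site_id", "label"))
  as.matrix(as.data.frame(tab)[, fn, drop = FALSE])
}

#' Replace the feature columns of a trial table
#' @param tab A `trial_table`.
#' @param X Numeric matrix with the same dimensions/colnames as
#'   `feature_matrix(tab)`.
#' @return The modified `trial_table`.
#' @export
set_features <- function(tab, X) {
  stopifnot(identical(colnames(X), setdiff(names(tab), c("site_id", "label"))))
  for (j in colnames(X)) tab[[j]] <- X[, j]
  tab
}

#' @export
print.trial_table <- function(x, ...) {
  nf <- ncol(x) - 2L
  cat(sprintf("trial_table: %d records x %d features, %d sites, %.1f%% positive, %d missing cells\n",
              nrow(x), nf, nlevels(x$site_id),
              100 * mean(x$label), sum(is.na(feature_matrix(x)))))
  invisible(x)
}

# CSV round trip -------------------------------------------------------------

#' Write a trial table to CSV
#'
#' Fixed header `site_id,label,<39 feature names>`; missing cells are
#' written empty; `"."` decimal separator; UTF-8.
#'
#' @param tab A `trial_table`.
#' @param path Output file path.
#' @export
write_trial_table <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = FALSE, na = "",
            fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Read a trial table from CSV
#' @param path CSV file written by [write_trial_table()] (empty cells = NA).
#' @return A `trial_table`.
#' @export
read_trial_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, na.strings = "",
                 fileEncoding = "UTF-8")
  trial_table(df$site_id, df$label,
              df[, setdiff(names(df), c("site_id", "label")), drop = FALSE])
}
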