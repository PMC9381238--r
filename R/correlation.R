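# Pearson feature-label screening (point-biserial against the binary
# continuing/termination label).

#' Pearson correlation coefficient
#'
#' Direct two-pass evaluation of the product-moment correlation
#' `sum((x - xbar)(y - ybar)) / sqrt(sum((x - xbar)^2) sum((y - ybar)^2))`.
#' With a 0/1 `y` this is the point-biserial correlation.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return The correlation, in \[-1, 1\].
#' @export
#' @examples
#' pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need at least 3 observations")
  dx <- x - mean(x); dy <- y - mean(y)
  vx <- sum(dx^2); vy <- sum(dy^2)
  if (vx == 0 || vy == 0)
    stop("correlation undefined for a constant vector")
  sum(dx * dy) / sqrt(vx * vy)
}

#' Feature-label correlation report
#'
#' Computes the point-biserial correlation of each feature column against
#' the binary label, ranks features by absolute correlation, and flags the
#' strongly related ones (|r| at or above `flag_threshold`).
#'
#' @param tab A complete `trial_table` with both label classes present.
#' @param flag_threshold Absolute-correlation flagging cut-off
#'   (default 0.07).
#' @return A `correlation_report`: data frame with columns `feature`, `r`,
#'   `abs_r`, `rank`, `flagged`, ordered by rank; attribute `n` (records
#'   used).
#' @export
correlation_report <- function(tab, flag_threshold = 0.07) {
  X <- feature_matrix(tab)
  if (anyNA(X)) stop("correlation_report requires a complete table")
  y <- tab$label
  if (length(unique(y)) < 2)
    stop("correlation undefined: label has a single class")
  r <- vapply(seq_len(ncol(X)), function(j) pearson(X[, j], y), numeric(1))
  rep <- data.frame(feature = colnames(X), r = r, abs_r = abs(r))
  rep <- rep[order(-rep$abs_r, rep$feature), ]
  rep$rank <- seq_len(nrow(rep))
  rep$flagged <- rep$abs_r >= flag_threshold
  rownames(rep) <- NULL
  attr(rep, "n") <- nrow(X)
  class(rep) <- c("correlation_report", "data.frame")
  rep
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("correlation_report on %d records; top features by |r|:\n",
              attr(x, "n")))
  print.data.frame(head(as.data.frame(x), 8), digits = 3)
  invisible(x)
}
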