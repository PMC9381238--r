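# Synthetic multi-site variety-trial data with calibrated feature-label
# correlations. Records are generated from a latent-score label model:
# standardized features z_j (climate columns share site-level effects),
# latent s = sum_j w_j z_j + eps with eps ~ N(0,1), label = 1{s > t}.
# For jointly Gaussian (z_j, s) the point-biserial correlation of z_j with
# the thresholded label has the closed form
#   r_j = (w_j / sigma_s) * phi(t/sigma_s) / sqrt(p (1 - p)),
# which is inverted exactly to find loadings w reproducing a requested
# correlation profile at a requested positive rate.

#' Default feature-label correlation targets
#'
#' The published correlation profile of the 39 trial features against the
#' continuing/termination label (relative change of yield dominant at
#' 0.346; variance of relative humidity, mean relative humidity, mean
#' sunshine time, mean minimum temperature and empty stalk rate secondary).
#'
#' @return Named numeric vector of length 39 (canonical feature order).
#' @export
default_target_corr <- function() {
  r <- c(LB = -0.041, LR = -0.059, IR = -0.052, GSD = -0.015, PH = 0.014,
         EH = 0.016, ESR = -0.062, DP = -0.017, ER = 0.013, HGW = 0.047,
         EL = 0.038, BTL = -0.011, FEF = 0.033, CAY = 0.045, RCY = 0.346,
         AMaxT = 0.046, VMaxT = 0.044, AAT = -0.053, VAT = -0.041,
         AMinT = 0.071, VMinT = -0.046, ATD = -0.054, VTD = -0.058,
         AGP = -0.023, VGP = -0.018, ARH = -0.079, VRH = -0.087,
         AP = 0.025, VP = 0.010, AMWS = -0.046, VMWS = -0.062,
         AAWS = -0.012, VAWS = -0.012, AWDA = 0.048, VWDA = 0.024,
         AST = -0.073, VST = -0.042, AWL = -0.048, VWL = -0.027)
  r[trial_feature_names()]
}

# Plausible trait/climate marginals (location, scale). Only the correlation
# structure is asserted anywhere; these fix units and keep variance-type
# columns safely positive (location/scale >= 6).
feature_marginals <- function() {
  m <- rbind(
    LB = c(12, 5), LR = c(5, 3), IR = c(3, 2), GSD = c(8, 4),
    PH = c(260, 20), EH = c(105, 15), ESR = c(4, 2.5), DP = c(125, 10),
    ER = c(6, 3), HGW = c(27, 3), EL = c(18, 2), BTL = c(1.5, 0.8),
    FEF = c(750, 100), CAY = c(420, 60), RCY = c(0, 8),
    AMaxT = c(28, 3), VMaxT = c(20, 3), AAT = c(22, 2.5), VAT = c(15, 2.2),
    AMinT = c(16, 3), VMinT = c(18, 2.8), ATD = c(11, 2), VTD = c(8, 1.2),
    AGP = c(950, 40), VGP = c(30, 4.5), ARH = c(65, 10), VRH = c(110, 16),
    AP = c(3.5, 1.5), VP = c(60, 9), AMWS = c(6, 1.5), VMWS = c(4, 0.6),
    AAWS = c(2.2, 0.6), VAWS = c(1.5, 0.22), AWDA = c(180, 40),
    VWDA = c(4000, 600), AST = c(7, 1.5), VST = c(9, 1.4),
    AWL = c(2.5, 0.7), VWL = c(1.2, 0.18))
  colnames(m) <- c("mean", "sd")
  m[trial_feature_names(), ]
}

#' Configuration for the synthetic trial-data generator
#'
#' @param n_records Number of trial records (default 10000).
#' @param n_sites Number of trial sites (default 14).
#' @param target_corr Named vector of target point-biserial correlations of
#'   each feature with the binary label; names must be exactly the 39
#'   canonical feature names; magnitudes must be < 0.6. Default
#'   [default_target_corr()].
#' @param positive_rate Fraction of "continuing test" (label 1) records,
#'   in (0, 1). Default 0.5.
#' @param site_spread Ratio of between-site to within-site variance for
#'   climate columns, >= 0. Default 0.25.
#' @param outlier_rate Fraction of feature cells displaced to extreme
#'   values, in \[0, 0.05\]. Default 0.005.
#' @param missing_rate Fraction of feature cells set missing, in
#'   \[0, 0.05\]. Default 0.01.
#' @param seed Integer RNG seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_records = 10000, n_sites = 14,
                             target_corr = default_target_corr(),
                             positive_rate = 0.5, site_spread = 0.25,
                             outlier_rate = 0.005, missing_rate = 0.01,
                             seed = 1L) {
  stopifnot(n_records >= 1, n_sites >= 1, n_sites <= n_records,
            positive_rate > 0, positive_rate < 1, site_spread >= 0,
            outlier_rate >= 0, outlier_rate <= 0.05,
            missing_rate >= 0, missing_rate <= 0.05)
  if (!setequal(names(target_corr), trial_feature_names()))
    stop("target_corr names must be exactly the 39 canonical feature names")
  target_corr <- target_corr[trial_feature_names()]
  if (any(abs(target_corr) >= 0.6))
    stop("infeasible target correlation (|r| >= 0.6) for feature(s): ",
         paste(names(target_corr)[abs(target_corr) >= 0.6], collapse = ", "))
  structure(list(n_records = as.integer(n_records),
                 n_sites = as.integer(n_sites), target_corr = target_corr,
                 positive_rate = positive_rate, site_spread = site_spread,
                 outlier_rate = outlier_rate, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Calibrate latent-score loadings for a correlation profile
#'
#' Inverts the closed-form point-biserial correlation of the threshold
#' label model: with standardized Gaussian features, unit latent noise and
#' positive rate p, a loading vector w yields
#' r_j = (w_j/sigma_s) * dnorm(q)/sqrt(p(1-p)), q = qnorm(1-p),
#' sigma_s^2 = sum(w^2) + 1. Solving for w given r is exact.
#'
#' @param target_corr Named numeric vector of target correlations.
#' @param positive_rate Target positive-class fraction in (0, 1).
#' @return List with loadings `w`, latent scale `sigma_s`, latent threshold
#'   `threshold`, and the attenuation constant `c` linking latent and
#'   point-biserial correlations.
#' @export
calibrate_loadings <- function(target_corr, positive_rate) {
  q <- qnorm(1 - positive_rate)
  cc <- dnorm(q) / sqrt(positive_rate * (1 - positive_rate))
  rho <- target_corr / cc          # required corr(z_j, latent score)
  ss <- sum(rho^2)
  if (ss >= 0.995) {
    worst <- names(which.max(abs(target_corr)))
    stop("calibration infeasible: requested correlations too large ",
         "(latent R^2 ", signif(ss, 3), " >= 1); largest target is ", worst)
  }
  sigma_s <- 1 / sqrt(1 - ss)
  list(w = rho * sigma_s, sigma_s = sigma_s, threshold = q * sigma_s, c = cc)
}

#' Generate a synthetic variety-trial table
#'
#' Draws `n_records` records over `n_sites` sites. Climate columns carry a
#' shared site-level effect (variance ratio `site_spread`) so records from
#' the same site are closer in climate space; trait columns are independent
#' across records. Labels come from the calibrated latent threshold model,
#' so each feature's empirical correlation with the label approximates its
#' target (within about +/-0.05 at n = 10000). If the configured artifact
#' rates are positive, outliers and missing cells are injected afterwards
#' (see [inject_artifacts()]); injected positions are recorded in the
#' attributes `injected_outliers` / `injected_missing`.
#'
#' @param config A [synthetic_config()].
#' @return A `trial_table` with attributes `config`, `injected_outliers`,
#'   `injected_missing`.
#' @export
#' @examples
#' tab <- generate_trial_table(synthetic_config(n_records = 200, seed = 1))
#' dim(feature_matrix(tab))
generate_trial_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cal <- calibrate_loadings(config$target_corr, config$positive_rate)
  n <- config$n_records
  fn <- trial_feature_names()
  clim <- climate_feature_names()
  set.seed(config$seed)

  site <- factor(sample.int(config$n_sites, n, replace = TRUE),
                 levels = seq_len(config$n_sites),
                 labels = sprintf("S%02d", seq_len(config$n_sites)))

  tau2 <- config$site_spread
  Z <- matrix(0, n, 39, dimnames = list(NULL, fn))
  for (j in fn) {
    if (j %in% clim && tau2 > 0) {
      u <- rnorm(config$n_sites, 0, sqrt(tau2))   # site-level effect
      Z[, j] <- (u[as.integer(site)] + rnorm(n)) / sqrt(1 + tau2)
    } else {
      Z[, j] <- rnorm(n)
    }
  }

  s <- drop(Z %*% cal$w) + rnorm(n)
  # threshold at the empirical quantile: site-level climate effects shift
  # the latent score jointly, so a fixed Gaussian quantile would let the
  # realized positive rate drift; the empirical cut pins it exactly
  label <- as.integer(s > stats::quantile(s, 1 - config$positive_rate,
                                          names = FALSE))

  marg <- feature_marginals()
  X <- sweep(sweep(Z, 2, marg[, "sd"], "*"), 2, marg[, "mean"], "+")
  vcols <- grep("^V", clim, value = TRUE)
  X[, vcols] <- pmax(X[, vcols], 0)

  tab <- trial_table(site, label, X)
  attr(tab, "config") <- config
  if (config$outlier_rate > 0 || config$missing_rate > 0)
    tab <- inject_artifacts(tab, config$outlier_rate, config$missing_rate,
                            seed = config$seed + 1L)
  tab
}

#' Inject outliers and missing cells into a trial table
#'
#' Marks the requested fractions of feature cells: outlier cells are
#' displaced to the column mean plus a random sign times 6-10 within-column
#' standard deviations (computed on the clean table); missing cells become
#' `NA`. The two sets are disjoint and their positions are recorded in the
#' attributes `injected_outliers` and `injected_missing` (data frames with
#' `row`, `col`) so that downstream screening can be audited.
#'
#' @param tab A clean `trial_table`.
#' @param outlier_rate Fraction of cells to displace, in \[0, 0.05\].
#' @param missing_rate Fraction of cells to blank, in \[0, 0.05\].
#' @param seed Integer RNG seed.
#' @return The modified `trial_table`.
#' @export
inject_artifacts <- function(tab, outlier_rate, missing_rate, seed = 1L) {
  stopifnot(outlier_rate >= 0, outlier_rate <= 0.05,
            missing_rate >= 0, missing_rate <= 0.05)
  X <- feature_matrix(tab)
  n_cells <- length(X)
  n_out <- round(outlier_rate * n_cells)
  n_mis <- round(missing_rate * n_cells)
  set.seed(seed)
  cells <- sample.int(n_cells, n_out + n_mis)
  out_cells <- cells[seq_len(n_out)]
  mis_cells <- cells[n_out + seq_len(n_mis)]

  col_mean <- colMeans(X)
  col_sd <- apply(X, 2, sd)
  if (n_out > 0) {
    jj <- (out_cells - 1L) %/% nrow(X) + 1L
    sgn <- sample(c(-1, 1), n_out, replace = TRUE)
    # variance-type climate columns are non-negative: displace upwards only
    sgn[grepl("^V", colnames(X)[jj]) & colnames(X)[jj] %in% climate_feature_names()] <- 1
    X[out_cells] <- col_mean[jj] + sgn * (6 + 4 * runif(n_out)) * col_sd[jj]
  }
  if (n_mis > 0) X[mis_cells] <- NA_real_

  idx_df <- function(cells)
    data.frame(row = (cells - 1L) %% nrow(X) + 1L,
               col = colnames(X)[(cells - 1L) %/% nrow(X) + 1L])
  out <- set_features(tab, X)
  attr(out, "injected_outliers") <- idx_df(out_cells)
  attr(out, "injected_missing") <- idx_df(mis_cells)
  out
}
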