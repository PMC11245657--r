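#' Concordance (C) statistic for case versus control scores
#'
#' The probability that a randomly chosen case receives a higher score than
#' a randomly chosen control, with ties counting one half — identical to the
#' area under the ROC curve. The confidence interval uses the DeLong
#' placement-variance estimator on the Wald scale, clipped to \[0, 1\].
#'
#' @param scores_cases Numeric scores of the cases.
#' @param scores_controls Numeric scores of the controls.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return List with `c_statistic`, `se`, `ci_lower`, `ci_upper`.
#' @export
c_statistic <- function(scores_cases, scores_controls, conf_level = 0.95) {
  if (length(scores_cases) == 0L || length(scores_controls) == 0L) {
    rr_stop("both score groups must be nonempty")
  }
  x <- as.numeric(scores_cases)
  y <- as.numeric(scores_controls)
  if (anyNA(x) || anyNA(y)) rr_stop("scores must not contain missing values")
  m <- length(x); n <- length(y)
  # midrank formulation (DeLong, DeLong & Clarke-Pearson)
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n          # placements of cases
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m  # placements of controls
  auc <- mean(v10)
  var_auc <- if (m > 1L) stats::var(v10) / m else 0
  var_auc <- var_auc + if (n > 1L) stats::var(v01) / n else 0
  se <- sqrt(var_auc)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(c_statistic = auc, se = se,
       ci_lower = max(0, auc - zq * se),
       ci_upper = min(1, auc + zq * se))
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes; lower is better, and a constant prediction of 0.5 scores 0.25.
#'
#' @param predicted Predicted probabilities in \[0, 1\].
#' @param outcomes Binary outcomes (0/1).
#' @return The Brier score.
#' @export
brier_score <- function(predicted, outcomes) {
  if (length(predicted) != length(outcomes)) {
    rr_stop("'predicted' and 'outcomes' must have equal length")
  }
  if (length(predicted) == 0L) rr_stop("inputs must be nonempty")
  if (any(predicted < 0 | predicted > 1, na.rm = TRUE)) {
    rr_stop("'predicted' must lie in [0, 1]")
  }
  mean((predicted - outcomes)^2)
}

#' Decile-style calibration bins
#'
#' Ranks subjects by predicted risk (stable sort: ties keep row order) and
#' partitions them into `n_bins` near-equal groups; reports, per bin, the
#' count, the mean predicted risk ("calibrated") and the observed outcome
#' rate ("uncalibrated"). With constant predictions the partition falls back
#' to row order, so all bins share the same predicted mean.
#'
#' @param predicted Predicted probabilities.
#' @param outcomes Binary outcomes aligned with `predicted`.
#' @param n_bins Number of risk groups (default 10).
#' @return Data frame with columns `bin`, `n`, `mean_predicted`,
#'   `observed_rate`.
#' @export
calibration_bins <- function(predicted, outcomes, n_bins = 10L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) rr_stop("'n_bins' must be at least 2")
  n <- length(predicted)
  if (length(outcomes) != n) rr_stop("length mismatch")
  if (n < n_bins) rr_stop("need at least one subject per bin")
  ord <- order(predicted)  # stable: ties stay in row order
  sizes <- diff(round(seq(0, n, length.out = n_bins + 1L)))
  bin <- factor(rep(seq_len(n_bins), times = sizes), levels = seq_len(n_bins))
  p <- predicted[ord]; y <- outcomes[ord]
  data.frame(
    bin = seq_len(n_bins),
    n = as.integer(sizes),
    mean_predicted = as.numeric(tapply(p, bin, mean)),
    observed_rate = as.numeric(tapply(y, bin, mean))
  )
}

#' Mean absolute error
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @return Mean of the absolute differences.
#' @export
mae <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) == 0L) {
    rr_stop("'predicted' and 'observed' must be nonempty and of equal length")
  }
  mean(abs(predicted - observed))
}

#' Root mean square error
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @return Square root of the mean squared difference.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) == 0L) {
    rr_stop("'predicted' and 'observed' must be nonempty and of equal length")
  }
  sqrt(mean((predicted - observed)^2))
}

#' Overlap of the top-k high-risk regions
#'
#' Identifies the k regions with the highest predicted and the highest
#' observed rates and returns the fraction of overlap. Rate ties are broken
#' deterministically by region identifier (ascending), so repeated runs
#' agree.
#'
#' @param predicted_rates Named numeric vector of predicted rates, names are
#'   region identifiers.
#' @param observed_rates Named numeric vector of observed rates over the
#'   same regions.
#' @param k Number of top regions to compare (default 5).
#' @return Overlap proportion in `{0, 1/k, ..., 1}`.
#' @export
top_k_overlap <- function(predicted_rates, observed_rates, k = 5L) {
  k <- as.integer(k)
  if (is.null(names(predicted_rates)) || is.null(names(observed_rates))) {
    rr_stop("rate vectors must be named by region")
  }
  if (!setequal(names(predicted_rates), names(observed_rates))) {
    rr_stop("predicted and observed rates must cover the same regions")
  }
  if (length(predicted_rates) < k) {
    rr_stop(sprintf("need at least k = %d regions", k))
  }
  top <- function(v) {
    ord <- order(-v, names(v))
    names(v)[ord][seq_len(k)]
  }
  length(intersect(top(predicted_rates), top(observed_rates))) / k
}
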