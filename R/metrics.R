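#' Concordance index for continuous affinity predictions
#'
#' Over every ordered pair of observations whose true affinities differ
#' strictly, the concordance index scores 1 when the predictions preserve
#' the ordering, 0.5 when they tie, and 0 when they invert it, and
#' averages over the qualifying pairs:
#' `CI = (1/Z) * sum over (truth_i > truth_j) of h(pred_i - pred_j)`,
#' with `h` the step function (1 / 0.5 / 0 for positive / zero /
#' negative) and `Z` the number of qualifying pairs.  Ties in the truths
#' are excluded from `Z`.  A CI of 1 means perfectly preserved ranking,
#' 0.5 is chance level.
#'
#' @param truth Numeric vector of observed affinities.
#' @param pred Numeric vector of predicted affinities, same length.
#' @param block Internal chunk size controlling peak memory of the
#'   pairwise computation.
#' @return The concordance index in `[0, 1]`.
#' @examples
#' concordance_index(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 5/6
#' @export
concordance_index <- function(truth, pred, block = 2048L) {
  truth <- as.numeric(truth); pred <- as.numeric(pred)
  n <- length(truth)
  if (length(pred) != n) stop("truth and pred must have equal length")
  if (n < 2L) stop("need at least 2 observations")
  if (any(!is.finite(truth)) || any(!is.finite(pred))) {
    stop("non-finite values in truth or pred")
  }
  num <- 0; z <- 0
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    dt <- outer(truth[rows], truth, "-")
    dp <- outer(pred[rows], pred, "-")
    qual <- dt > 0
    z <- z + sum(qual)
    num <- num + sum(ifelse(dp[qual] > 0, 1, ifelse(dp[qual] == 0, 0.5, 0)))
  }
  if (z == 0) stop("all true affinities are tied: concordance undefined")
  num / z
}

#' Mean squared error
#'
#' @param truth,pred Numeric vectors of equal length.
#' @return Mean of squared differences.
#' @export
mean_squared_error <- function(truth, pred) {
  truth <- as.numeric(truth); pred <- as.numeric(pred)
  if (length(truth) != length(pred)) stop("truth and pred must have equal length")
  if (length(truth) < 1L) stop("need at least 1 observation")
  mean((truth - pred)^2)
}

#' Pearson correlation between truth and predictions
#'
#' The usual product-moment correlation `cov(p, y) / (sd(p) * sd(y))`;
#' the ratio is invariant to the sample-vs-population variance
#' convention.  Constant input is rejected (zero variance makes the
#' correlation undefined).
#'
#' @param truth,pred Numeric vectors of equal length >= 2.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_cor <- function(truth, pred) {
  truth <- as.numeric(truth); pred <- as.numeric(pred)
  if (length(truth) != length(pred)) stop("truth and pred must have equal length")
  if (length(truth) < 2L) stop("need at least 2 observations")
  if (stats::var(truth) == 0 || stats::var(pred) == 0) {
    stop("zero variance in truth or pred: correlation undefined")
  }
  stats::cor(truth, pred)
}

#' Bundle MSE, concordance index and Pearson correlation
#'
#' @param truth,pred Numeric vectors of equal length.
#' @return Object of class `metrics_report`: list with `mse`, `ci`,
#'   `pearson` and `n`.
#' @export
evaluate_predictions <- function(truth, pred) {
  structure(list(mse = mean_squared_error(truth, pred),
                 ci = concordance_index(truth, pred),
                 pearson = pearson_cor(truth, pred),
                 n = length(truth)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d\n  MSE     = %.6f\n  CI      = %.6f\n  Pearson = %.6f\n",
              x$n, x$mse, x$ci, x$pearson))
  invisible(x)
}

#' Write a metrics report as a one-row CSV
#'
#' @param report A [evaluate_predictions()] result.
#' @param path Output file.
#' @export
write_metrics_csv <- function(report, path) {
  utils::write.csv(data.frame(n = report$n, mse = report$mse,
                              ci = report$ci, pearson = report$pearson),
                   path, row.names = FALSE)
  invisible(path)
}
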