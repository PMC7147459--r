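#' Descriptive statistics of an encoded feature matrix
#'
#' Columnwise means and variances (population convention) of a protein
#' feature matrix, plus quartiles of the per-feature mean scores and a
#' fixed-width histogram of all matrix values.  These are the summaries
#' used to compare encodings: a useful peptide encoding shows modest
#' per-feature scores with real spread between proteins, rather than a
#' few saturated features or a mass of near-zero ones.
#'
#' @param mat Numeric matrix from [encode_corpus()] (rows = proteins).
#' @param bin_width Histogram bin width (default 0.025, the score
#'   interval at which dipeptide encodings are typically inspected).
#' @return Object of class `feature_stats`: list with `mean`, `variance`
#'   (per feature), `quartiles` (of the per-feature means), `breaks` and
#'   `counts` (histogram of all values), `n_proteins`, `n_features`.
#' @export
feature_stats <- function(mat, bin_width = 0.025) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 1L || ncol(mat) < 1L) stop("feature_stats needs a non-empty matrix")
  n <- nrow(mat)
  mu <- colMeans(mat)
  vr <- colMeans(mat^2) - mu^2  # population variance
  vr[vr < 0] <- 0
  top <- max(max(mat), 0.45)
  breaks <- seq(0, ceiling(top / bin_width) * bin_width + bin_width,
                by = bin_width)
  counts <- as.integer(table(cut(as.vector(mat), breaks = breaks,
                                 include.lowest = TRUE, right = FALSE)))
  structure(list(mean = mu, variance = vr,
                 quartiles = stats::quantile(mu, c(0.25, 0.5, 0.75)),
                 breaks = breaks, counts = counts,
                 n_proteins = n, n_features = ncol(mat)),
            class = "feature_stats")
}

#' @export
print.feature_stats <- function(x, ...) {
  cat("<feature_stats> ", x$n_features, " features x ", x$n_proteins,
      " proteins\n  mean score quartiles: ",
      paste(signif(x$quartiles, 4), collapse = " / "),
      "\n  score range [", signif(min(x$mean), 4), ", ",
      signif(max(x$mean), 4), "]\n", sep = "")
  invisible(x)
}

#' Random-forest variable importance of peptide features
#'
#' Fits a seeded random-forest regressor of the affinities on the
#' encoded peptide features and reports per-feature importance,
#' normalized to sum to one.  The default importance is the mean
#' decrease in node impurity (residual sum of squares); permutation
#' importance is available behind `importance = "permutation"`, with
#' negative values clamped to zero before normalization.
#'
#' @param features Numeric matrix (rows = observations, columns =
#'   peptide features; column names are the peptide labels).
#' @param affinities Numeric response vector, one per row.
#' @param n_trees Number of trees (default 10000; reduce for quick
#'   runs).
#' @param seed Integer seed.
#' @param importance `"impurity"` (default) or `"permutation"`.
#' @return Object of class `vim_report`: list with `importance` (named,
#'   sums to 1), `n_nonzero`, `n_trees`, `seed`, `importance_type` and
#'   `rf_params` (the forest hyperparameters used).
#' @export
compute_vim <- function(features, affinities, n_trees = 10000, seed = 1,
                        importance = c("impurity", "permutation")) {
  importance <- match.arg(importance)
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need at least 2 observations")
  if (length(affinities) != nrow(features)) {
    stop("affinities length must match feature rows")
  }
  if (stats::var(affinities) == 0) {
    stop("constant affinities: importance undefined")
  }
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  fit <- ranger::ranger(
    x = as.data.frame(features), y = as.numeric(affinities),
    num.trees = n_trees, importance = importance,
    seed = as.integer(seed), num.threads = 1L
  )
  imp <- fit$variable.importance
  if (importance == "permutation") imp[imp < 0] <- 0
  total <- sum(imp)
  if (total <= 0) stop("all importances are zero")
  imp <- imp / total
  structure(list(importance = imp,
                 n_nonzero = sum(imp > 0),
                 n_trees = as.integer(n_trees),
                 seed = as.integer(seed),
                 importance_type = importance,
                 rf_params = list(mtry = fit$mtry,
                                  min_node_size = fit$min.node.size,
                                  num_trees = fit$num.trees)),
            class = "vim_report")
}

#' @export
print.vim_report <- function(x, ...) {
  top <- sort(x$importance, decreasing = TRUE)[1:min(5, length(x$importance))]
  cat("<vim_report> ", length(x$importance), " features, ",
      x$n_nonzero, " with non-zero importance (", x$n_trees, " trees, ",
      x$importance_type, ")\n  top: ",
      paste(sprintf("%s (%.1f%%)", names(top), 100 * top), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Rank features by importance above a contribution threshold
#'
#' @param report A [compute_vim()] result.
#' @param threshold Minimum importance share to keep (default 0.005,
#'   i.e. contributions above 0.5%).
#' @return Data frame (`label`, `importance`, `rank`) sorted descending,
#'   with attribute `n_nonzero` carrying the count of features with any
#'   importance at all.
#' @export
rank_features <- function(report, threshold = 0.005) {
  stopifnot(inherits(report, "vim_report"))
  imp <- sort(report$importance, decreasing = TRUE)
  keep <- imp >= threshold
  out <- data.frame(label = names(imp)[keep],
                    importance = unname(imp[keep]),
                    rank = seq_len(sum(keep)),
                    stringsAsFactors = FALSE)
  attr(out, "n_nonzero") <- report$n_nonzero
  out
}

#' Arrange dipeptide importances as a 25 x 25 grid
#'
#' Rows are the first residue, columns the second, both in alphabet
#' order — the layout used for dipeptide-importance heatmaps.
#'
#' @param report A [compute_vim()] result over `25^2` dipeptide features.
#' @param alphabet A [peptide_alphabet()].
#' @return 25 x 25 numeric matrix with residue dimnames.
#' @export
vim_grid <- function(report, alphabet = peptide_alphabet()) {
  stopifnot(inherits(report, "vim_report"))
  if (length(report$importance) != 625L) {
    stop("vim_grid expects a dipeptide (625-feature) report")
  }
  letters <- unclass(alphabet)
  matrix(report$importance, nrow = 25, ncol = 25, byrow = TRUE,
         dimnames = list(first = letters, second = letters))
}

#' Write a variable-importance report as CSV (and optional grid TSV)
#'
#' @param report A [compute_vim()] result.
#' @param path Output CSV for the ranking.
#' @param grid_path Optional TSV path for the 25 x 25 dipeptide grid.
#' @param threshold Passed to [rank_features()]; use 0 to write all
#'   features.
#' @export
write_vim_csv <- function(report, path, grid_path = NULL, threshold = 0) {
  ranked <- rank_features(report, threshold)
  utils::write.csv(ranked, path, row.names = FALSE)
  if (!is.null(grid_path)) {
    utils::write.table(vim_grid(report), grid_path, sep = "\t",
                       quote = FALSE, col.names = NA)
  }
  invisible(path)
}
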