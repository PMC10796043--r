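#' Forest hyperparameters
#'
#' Constructs the tuning-parameter set shared by [regression_forest()],
#' [causal_forest()] and [instrumental_forest()].  Trees are grown on
#' household-level subsamples, each split into disjoint splitting and
#' estimation halves ("honesty"): split points are chosen on the splitting
#' half only, while leaf effects use the estimation half.
#'
#' @param n_trees Number of trees in the ensemble.  The default of 2,000 is a
#'   desk-scale compromise; production analyses of lottery-design data use an
#'   order of magnitude more (the estimator is invariant in expectation to the
#'   tree count, which controls only Monte-Carlo noise).
#' @param sample_fraction Fraction of households subsampled (without
#'   replacement) for each tree, in (0, 1].  A value of 1 leaves no
#'   out-of-bag trees for any observation.
#' @param honesty_fraction Fraction of each tree's subsample assigned to the
#'   splitting half, in (0, 1); the remainder forms the estimation half.
#' @param mtry Number of covariates considered at each split.  `NULL` (the
#'   default) resolves to `ceiling(sqrt(p))` at fit time.
#' @param min_node_size Minimum number of treated and of control
#'   estimation-half observations required in every leaf (for regression
#'   forests, the minimum total estimation-half count).
#' @param alpha_imbalance Minimum fraction of a node's splitting-half
#'   observations that must fall on each side of a split, in (0, 0.25].
#' @param imbalance_penalty Nonnegative penalty subtracted from the split
#'   criterion, scaled by `1/n_left + 1/n_right`.
#' @param seed Integer seed for the forest's internal random stream.
#'
#' @return An object of class `"forest_params"` (a validated named list).
#' @export
forest_params <- function(n_trees = 2000L,
                          sample_fraction = 0.5,
                          honesty_fraction = 0.5,
                          mtry = NULL,
                          min_node_size = 5L,
                          alpha_imbalance = 0.05,
                          imbalance_penalty = 0,
                          seed = 42L) {
  n_trees <- as.integer(n_trees)
  if (is.na(n_trees) || n_trees < 1L) {
    stop("n_trees must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(sample_fraction) || sample_fraction <= 0 ||
      sample_fraction > 1) {
    stop("sample_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(honesty_fraction) || honesty_fraction <= 0 ||
      honesty_fraction >= 1) {
    stop("honesty_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (!is.null(mtry)) {
    mtry <- as.integer(mtry)
    if (is.na(mtry) || mtry < 1L) stop("mtry must be >= 1", call. = FALSE)
  }
  min_node_size <- as.integer(min_node_size)
  if (is.na(min_node_size) || min_node_size < 1L) {
    stop("min_node_size must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(alpha_imbalance) || alpha_imbalance <= 0 ||
      alpha_imbalance > 0.25) {
    stop("alpha_imbalance must lie in (0, 0.25]", call. = FALSE)
  }
  if (!is.numeric(imbalance_penalty) || imbalance_penalty < 0) {
    stop("imbalance_penalty must be nonnegative", call. = FALSE)
  }
  structure(
    list(
      n_trees = n_trees,
      sample_fraction = sample_fraction,
      honesty_fraction = honesty_fraction,
      mtry = mtry,
      min_node_size = min_node_size,
      alpha_imbalance = alpha_imbalance,
      imbalance_penalty = imbalance_penalty,
      seed = as.integer(seed)
    ),
    class = "forest_params"
  )
}

#' @export
print.forest_params <- function(x, ...) {
  cat("Forest hyperparameters:\n")
  cat(sprintf("  trees: %d, sample fraction: %.3g, honesty fraction: %.3g\n",
              x$n_trees, x$sample_fraction, x$honesty_fraction))
  cat(sprintf("  mtry: %s, min node size: %d, alpha: %.3g, penalty: %.3g\n",
              if (is.null(x$mtry)) "ceil(sqrt(p))" else x$mtry,
              x$min_node_size, x$alpha_imbalance, x$imbalance_penalty))
  invisible(x)
}
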