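#' Honest regression forest
#'
#' Fits an honest, household-subsampled regression forest minimizing the
#' weighted within-leaf squared error.  Used throughout the package to
#' estimate nuisance functions: the marginal outcome mean m(x) and the
#' propensity of lottery selection e(x).
#'
#' @param X Numeric covariate matrix (no missing values).
#' @param y Numeric response.
#' @param weights Optional positive observation weights (default: unit).
#' @param clusters Optional cluster (household) identifiers; subsampling and
#'   the honesty split operate at cluster level.  Default: each row its own
#'   cluster.
#' @param params A [forest_params()] object.
#' @param seed Integer seed (default: `params$seed`).
#' @return An object of class `"regression_forest"` with a [predict] method.
#' @seealso [predict.regression_forest()]
#' @export
regression_forest <- function(X, y, weights = NULL, clusters = NULL,
                              params = forest_params(), seed = params$seed) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (anyNA(X) || anyNA(y)) {
    stop("missing values are not supported; clean the inputs first",
         call. = FALSE)
  }
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (n < 2L * params$min_node_size) {
    stop("need at least 2 * min_node_size observations", call. = FALSE)
  }
  weights <- weights %||% rep(1, n)
  clusters <- clusters %||% seq_len(n)
  hh <- as.integer(factor(clusters)) - 1L
  mtry <- params$mtry %||% ceiling(sqrt(ncol(X)))
  flat <- .hf_grow_forest(
    X, as.numeric(y), numeric(n), numeric(n), integer(n),
    as.numeric(weights), hh, max(hh) + 1L, 0L, params$n_trees,
    params$sample_fraction, params$honesty_fraction, as.integer(mtry),
    params$min_node_size, params$alpha_imbalance, params$imbalance_penalty,
    as.integer(seed))
  structure(
    list(forest = flat, X = X, y = as.numeric(y),
         weights = as.numeric(weights), hh = hh, clusters = clusters,
         params = params, seed = as.integer(seed)),
    class = "regression_forest")
}

#' Predict from an honest regression forest
#'
#' @param object A fitted [regression_forest()].
#' @param newdata Optional covariate matrix for new points.  When omitted,
#'   predictions are for the training sample; with `oob = TRUE` (the default
#'   in that case) each person's prediction aggregates only trees whose
#'   household-level subsample excluded their household, and persons covered
#'   by every tree receive a flagged `NA`.
#' @param oob Use out-of-bag aggregation for training-sample predictions.
#' @param ... Unused.
#' @return Numeric vector of predictions (`NA` where no out-of-bag tree is
#'   available), with attribute `n_trees_used`.
#' @export
predict.regression_forest <- function(object, newdata = NULL,
                                      oob = is.null(newdata), ...) {
  if (is.null(newdata)) {
    res <- if (oob) {
      .hf_predict_oob(object$forest, object$X, object$hh)
    } else {
      .hf_predict(object$forest, object$X)
    }
  } else {
    newdata <- as.matrix(newdata)
    storage.mode(newdata) <- "double"
    res <- .hf_predict(object$forest, newdata)
  }
  structure(res$value, n_trees_used = res$n_trees_used)
}

#' @export
print.regression_forest <- function(x, ...) {
  cat(sprintf(
    "Honest regression forest: %d trees, n = %d, p = %d, %d households\n",
    x$params$n_trees, nrow(x$X), ncol(x$X), max(x$hh) + 1L))
  invisible(x)
}
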