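#' Honest causal forest
#'
#' Fits the two-step honest causal forest.  Step one estimates the nuisance
#' functions by honest regression forests: the marginal outcome mean m(x)
#' (regressing Y on X) and the propensity of lottery selection e(x)
#' (regressing Z on X), both evaluated out-of-bag.  Step two locally centers
#' the data (Y - m, Z - e) and grows an ensemble of honest causal trees on
#' household-level subsamples, choosing each split to maximize the negative
#' expected-MSE criterion: the split-half-weighted sum of squared leaf
#' effects, minus `(1/N_tr + 1/N_est)` times the per-leaf variance penalty
#' `S2_treated/p + S2_control/(1-p)`.  Leaf effects are re-estimated on the
#' held-out estimation half as the weighted residual-on-residual ratio
#' `sum(w (Y-m)(Z-e)) / sum(w (Z-e)^2)`.
#'
#' Rows whose nuisance out-of-bag prediction is unavailable (their household
#' appeared in every nuisance tree's subsample) are dropped with a message;
#' the `kept` component records the retained row indices.  Propensities are
#' clamped to \[0.01, 0.99\] before centering and score construction.
#'
#' @param X Numeric covariate matrix.
#' @param Y Numeric outcome.
#' @param Z Binary treatment indicator (lottery selection for
#'   intent-to-treat analyses; a funnel flag for the uptake stages).
#' @param weights Optional positive survey weights.
#' @param clusters Optional household identifiers (subsampling unit).
#' @param params A [forest_params()].
#' @param seed Integer seed; nuisance fits and tree growth draw from
#'   substreams derived from it.
#' @return An object of class `"causal_forest"`: components include
#'   `predictions` (out-of-bag CATEs for the analysis rows), `nuisance`
#'   (with out-of-bag `m_hat` and clamped `e_hat`), `residuals`, `kept`,
#'   and the flat tree ensemble.
#' @seealso [fit_causal_forest()] for the sample-based interface,
#'   [predict.causal_forest()], [aipw_scores()], [calibration_test()]
#' @export
causal_forest <- function(X, Y, Z, weights = NULL, clusters = NULL,
                          params = forest_params(), seed = params$seed) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (anyNA(X) || anyNA(Y) || anyNA(Z)) {
    stop("missing values are not supported; clean the inputs first",
         call. = FALSE)
  }
  if (!all(Z %in% c(0, 1))) {
    stop("Z must be binary 0/1", call. = FALSE)
  }
  weights <- weights %||% rep(1, n)
  clusters <- clusters %||% seq_len(n)

  fit <- .hf_fit_centered_forest(
    X, as.numeric(Y), as.integer(Z), d = NULL, weights = as.numeric(weights),
    clusters = clusters, params = params, seed = seed, type = 1L)
  fit$call_type <- "causal_forest"
  class(fit) <- "causal_forest"
  fit
}

# shared fitting core for causal (type 1) and instrumental (type 2) forests
.hf_fit_centered_forest <- function(X, Y, Z, d, weights, clusters, params,
                                    seed, type) {
  n <- nrow(X)
  nuis_params <- params
  m_forest <- regression_forest(X, Y, weights, clusters, nuis_params,
                                seed = hf_substream(seed, "nuisance_m"))
  e_forest <- regression_forest(X, Z, weights, clusters, nuis_params,
                                seed = hf_substream(seed, "nuisance_e"))
  m_hat <- as.numeric(predict(m_forest, oob = TRUE))
  e_hat_raw <- as.numeric(predict(e_forest, oob = TRUE))
  d_hat <- NULL
  if (type == 2L) {
    d_forest <- regression_forest(X, d, weights, clusters, nuis_params,
                                  seed = hf_substream(seed, "nuisance_e"))
    d_hat <- as.numeric(predict(d_forest, oob = TRUE))
  }

  keep <- !is.na(m_hat) & !is.na(e_hat_raw)
  if (type == 2L) keep <- keep & !is.na(d_hat)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf(
      "dropping %d row(s) without out-of-bag nuisance predictions",
      n_dropped))
  }
  if (sum(keep) < 2L * params$min_node_size) {
    stop("too few rows with out-of-bag nuisance predictions", call. = FALSE)
  }
  kept <- which(keep)
  Xk <- X[kept, , drop = FALSE]
  Yk <- Y[kept]
  Zk <- Z[kept]
  wk <- weights[kept]
  cl <- clusters[kept]
  hh <- as.integer(factor(cl)) - 1L

  cen <- center_sample(
    Y = Yk, Z = Zk, D = if (type == 2L) d[kept] else NULL,
    nuisance = list(m_hat = m_hat[kept], e_hat = e_hat_raw[kept],
                    d_hat = if (type == 2L) d_hat[kept] else NULL))

  mtry <- params$mtry %||% ceiling(sqrt(ncol(Xk)))
  flat <- .hf_grow_forest(
    Xk, cen$y_res, cen$z_res,
    if (type == 2L) cen$d_res else numeric(length(kept)),
    as.integer(Zk), wk, hh, max(hh) + 1L, type, params$n_trees,
    params$sample_fraction, params$honesty_fraction, as.integer(mtry),
    params$min_node_size, params$alpha_imbalance, params$imbalance_penalty,
    as.integer(hf_substream(seed, "trees")))
  oob <- .hf_predict_oob(flat, Xk, hh)

  list(
    forest = flat,
    X = Xk, Y = Yk, Z = Zk, D = if (type == 2L) d[kept] else NULL,
    weights = wk, hh = hh, clusters = cl,
    nuisance = list(m_hat = m_hat[kept], e_hat = cen$e_hat,
                    e_hat_raw = e_hat_raw[kept],
                    d_hat = if (type == 2L) d_hat[kept] else NULL,
                    n_clamped = cen$n_clamped),
    m_forest = m_forest, e_forest = e_forest,
    residuals = cen[c("y_res", "z_res", "d_res")],
    predictions = oob$value,
    oob_trees_used = oob$n_trees_used,
    kept = kept, n_dropped = n_dropped,
    params = params, seed = as.integer(seed))
}

#' Locally center outcomes and treatment by out-of-bag nuisances
#'
#' Computes the residualized arrays used by the splitting criterion and the
#' locally weighted effect estimator: `Y - m_hat`, `Z - e_hat` and, for
#' instrumental analyses, `D - d_hat`.  Propensities are clamped to
#' \[0.01, 0.99\]; a warning reports how many values required clamping.
#'
#' @param Y,Z Outcome and binary treatment vectors.
#' @param D Optional realized-treatment vector (instrumental analyses).
#' @param nuisance List with out-of-bag `m_hat`, `e_hat` and optionally
#'   `d_hat`, aligned with `Y`.
#' @return List with `y_res`, `z_res`, `d_res` (or `NULL`), the clamped
#'   `e_hat`, and `n_clamped`.
#' @export
center_sample <- function(Y, Z, D = NULL, nuisance) {
  e_raw <- nuisance$e_hat
  n_clamped <- sum(e_raw < 0.01 | e_raw > 0.99)
  if (n_clamped > 0) {
    warning(sprintf("%d propensity value(s) outside (0.01, 0.99) clamped",
                    n_clamped), call. = FALSE)
  }
  e_hat <- clamp(e_raw, 0.01, 0.99)
  list(
    y_res = Y - nuisance$m_hat,
    z_res = Z - e_hat,
    d_res = if (!is.null(D)) D - nuisance$d_hat else NULL,
    e_hat = e_hat,
    n_clamped = n_clamped
  )
}

#' Fit a causal forest to an observational sample
#'
#' Sample-based interface to [causal_forest()]: selects the outcome and
#' treatment columns, extracts the covariate matrix, and carries the sample
#' (restricted to analysis rows) in the fitted object so that downstream
#' score aggregation and subgroup analyses stay aligned.
#'
#' @param sample An `hf_sample`.
#' @param outcome Outcome name (with or without the `y_` prefix), outcome
#'   index, or `"D"` to analyse insurance uptake itself.
#' @param treatment Treatment column: `"Z"` (intent-to-treat, default) or a
#'   funnel flag (`"applied"`, `"approved"`) for the uptake stages.
#' @param covariates Optional subset of covariates (unprefixed names).
#' @param params A [forest_params()].
#' @param seed Integer seed.
#' @return A `"causal_forest"` with additional components `sample`,
#'   `outcome` and `treatment`.
#' @export
fit_causal_forest <- function(sample, outcome, treatment = "Z",
                              covariates = NULL, params = forest_params(),
                              seed = params$seed) {
  stopifnot(inherits(sample, "hf_sample"))
  ycol <- resolve_outcome(sample, outcome)
  if (!treatment %in% c("Z", "applied", "approved")) {
    stop("treatment must be one of 'Z', 'applied', 'approved'", call. = FALSE)
  }
  X <- covariate_matrix(sample, covariates)
  fit <- causal_forest(
    X, sample[[ycol]], sample[[treatment]],
    weights = sample$weight, clusters = sample$household_id,
    params = params, seed = seed)
  fit$sample <- sample[fit$kept, , drop = FALSE]
  attr(fit$sample, "covariates") <- attr(sample, "covariates")
  attr(fit$sample, "outcomes") <- attr(sample, "outcomes")
  fit$outcome <- ycol
  fit$treatment <- treatment
  fit
}

resolve_outcome <- function(sample, outcome) {
  outs <- attr(sample, "outcomes")
  if (is.numeric(outcome)) {
    if (outcome < 1 || outcome > length(outs)) {
      stop("outcome index out of range", call. = FALSE)
    }
    return(outs[outcome])
  }
  if (outcome %in% c("D", "uptake")) return("D")
  if (outcome %in% c("applied", "approved")) return(outcome)
  if (outcome %in% outs) return(outcome)
  if (paste0("y_", outcome) %in% outs) return(paste0("y_", outcome))
  stop(sprintf("unknown outcome '%s'", outcome), call. = FALSE)
}

#' Predict conditional average treatment effects
#'
#' Evaluates the adaptive locally weighted estimator: for a query point x,
#' each tree contributes kernel weight `1/|leaf|` to the estimation-half
#' members of the leaf containing x, and the CATE is the ratio of the
#' kernel- and survey-weighted centered cross-moment to the centered
#' treatment second moment.  Out-of-bag mode (training points) uses only
#' trees whose subsample excluded the person's household.
#'
#' @param object A fitted [causal_forest()] or [instrumental_forest()].
#' @param newdata Optional covariate matrix of query points; omitted means
#'   the training sample.
#' @param oob Out-of-bag aggregation for training points (default when
#'   `newdata` is omitted).
#' @param ... Unused.
#' @return Numeric CATE vector (`NA` flags points with no usable tree or a
#'   degenerate denominator), with attribute `n_trees_used`.
#' @export
predict.causal_forest <- function(object, newdata = NULL,
                                  oob = is.null(newdata), ...) {
  if (is.null(newdata)) {
    if (oob) {
      return(structure(object$predictions,
                       n_trees_used = object$oob_trees_used))
    }
    res <- .hf_predict(object$forest, object$X)
  } else {
    newdata <- as.matrix(newdata)
    storage.mode(newdata) <- "double"
    if (ncol(newdata) != ncol(object$X)) {
      stop("newdata must have the training covariate columns", call. = FALSE)
    }
    res <- .hf_predict(object$forest, newdata)
  }
  structure(res$value, n_trees_used = res$n_trees_used)
}

#' Kernel weights of the locally weighted CATE estimator
#'
#' Returns the normalized forest kernel weights alpha_i(x) for one query
#' point: the average over (usable) trees of `1/|leaf|` for estimation-half
#' members sharing the query's leaf.  Retained weights are nonnegative and
#' sum to one.
#'
#' @param object A fitted [causal_forest()] or [instrumental_forest()].
#' @param x Single covariate vector (query point).
#' @param exclude_household Optional household identifier whose trees to
#'   exclude (out-of-bag evaluation).
#' @return List with `alpha` (length = analysis sample size) and
#'   `n_trees_used`.
#' @export
alpha_weights <- function(object, x, exclude_household = NULL) {
  hh_code <- -1L
  if (!is.null(exclude_household)) {
    hh_code <- match(exclude_household, sort(unique(object$clusters))) - 1L
    if (is.na(hh_code)) {
      stop("exclude_household not present in the training sample",
           call. = FALSE)
    }
  }
  .hf_alpha(object$forest, as.numeric(x), as.integer(hh_code))
}

#' Depth-weighted split-count variable importance
#'
#' Scores each covariate by a decaying weighted share of split counts:
#' `score_j` is proportional to the sum over depths d of
#' `d^-decay_exponent` times covariate j's share of all splits at depth d,
#' normalized to sum to one.
#'
#' @param object A fitted forest.
#' @param decay_exponent Depth decay (default 2).
#' @param max_depth Deepest split level counted (default 4).
#' @return Named numeric vector of importance scores summing to one.
#' @export
variable_importance <- function(object, decay_exponent = 2, max_depth = 4) {
  flat <- object$forest
  p <- flat$n_features
  nm <- colnames(object$X) %||% paste0("x", seq_len(p))
  internal <- flat$node_var >= 0 & flat$node_depth <= max_depth
  if (!any(internal)) {
    warning("forest contains no splits; returning uniform importances",
            call. = FALSE)
    return(stats::setNames(rep(1 / p, p), nm))
  }
  score <- numeric(p)
  for (d in seq_len(max_depth)) {
    at_d <- internal & flat$node_depth == d
    tot <- sum(at_d)
    if (tot == 0) next
    counts <- tabulate(flat$node_var[at_d] + 1L, nbins = p)
    score <- score + d^(-decay_exponent) * counts / tot
  }
  stats::setNames(score / sum(score), nm)
}

#' @export
print.causal_forest <- function(x, ...) {
  kind <- if (inherits(x, "instrumental_forest")) {
    "Honest instrumental forest"
  } else {
    "Honest causal forest"
  }
  cat(sprintf("%s: %d trees, n = %d (%d dropped), p = %d, %d households\n",
              kind, x$params$n_trees, nrow(x$X), x$n_dropped, ncol(x$X),
              max(x$hh) + 1L))
  if (!is.null(x$outcome)) {
    cat(sprintf("  outcome: %s, treatment: %s\n", x$outcome,
                x$treatment %||% "Z"))
  }
  tau <- x$predictions[!is.na(x$predictions)]
  cat(sprintf("  out-of-bag CATE: mean %.4g, sd %.4g\n", mean(tau),
              stats::sd(tau)))
  invisible(x)
}

#' Summarize a causal forest
#'
#' Aggregates the forest into the doubly robust average treatment effect
#' (AIPW score mean with household-cluster-robust standard error) and the
#' omnibus calibration test for effect heterogeneity.
#'
#' @param object A fitted [causal_forest()].
#' @param ... Unused.
#' @return List of class `"summary.causal_forest"` with `ate` (an
#'   [average_effect()] estimate) and `calibration` (a [calibration_test()]
#'   result).
#' @export
summary.causal_forest <- function(object, ...) {
  scores <- aipw_scores(object)
  out <- list(ate = average_effect(scores),
              calibration = calibration_test(object),
              outcome = object$outcome %||% "Y")
  class(out) <- "summary.causal_forest"
  out
}

#' @export
print.summary.causal_forest <- function(x, ...) {
  cat(sprintf("Causal forest summary (outcome: %s)\n", x$outcome))
  cat("ATE (AIPW, cluster-robust):\n")
  print(x$ate)
  cat("Heterogeneity calibration:\n")
  print(x$calibration)
  invisible(x)
}

#' @export
plot.causal_forest <- function(x, ...) {
  tau <- x$predictions[!is.na(x$predictions)]
  graphics::hist(tau, breaks = 40, col = "grey80", border = "white",
                 main = "Out-of-bag individualized effects",
                 xlab = expression(hat(tau)(x)), ...)
  graphics::abline(v = mean(tau), lty = 2)
  invisible(x)
}
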