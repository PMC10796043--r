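#' Honest instrumental forest
#'
#' Instrumental-variable analogue of [causal_forest()] for estimating the
#' effect of realized treatment (insurance enrollment D) using the
#' randomized lottery Z as an instrument.  Outcome, treatment and instrument
#' are each centered by out-of-bag regression forests; honest trees are then
#' grown to maximize heterogeneity of the local IV estimand, and the
#' prediction at x is the kernel-weighted ratio
#' `sum(alpha w (Z - z_hat)(Y - y_hat)) / sum(alpha w (Z - z_hat)(D - d_hat))`.
#' The instrument and treatment nuisance forests share one seed stream, so
#' under perfect compliance (D identical to Z) the fit coincides exactly
#' with the causal forest.
#'
#' @inheritParams causal_forest
#' @param D Binary realized-treatment vector.
#' @return An object of class `c("instrumental_forest", "causal_forest")`.
#' @export
instrumental_forest <- function(X, Y, D, Z, weights = NULL, clusters = NULL,
                                params = forest_params(),
                                seed = params$seed) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (anyNA(X) || anyNA(Y) || anyNA(Z) || anyNA(D)) {
    stop("missing values are not supported; clean the inputs first",
         call. = FALSE)
  }
  if (!all(Z %in% c(0, 1)) || !all(D %in% c(0, 1))) {
    stop("Z and D must be binary 0/1", call. = FALSE)
  }
  weights <- weights %||% rep(1, n)
  clusters <- clusters %||% seq_len(n)
  fit <- .hf_fit_centered_forest(
    X, as.numeric(Y), as.integer(Z), d = as.numeric(D),
    weights = as.numeric(weights), clusters = clusters, params = params,
    seed = seed, type = 2L)
  fit$call_type <- "instrumental_forest"
  class(fit) <- c("instrumental_forest", "causal_forest")
  fit
}

#' @rdname instrumental_forest
#' @param sample An `hf_sample` (uses its `D` column as treatment and `Z`
#'   as instrument).
#' @param outcome Outcome name or index, as in [fit_causal_forest()].
#' @param covariates Optional covariate subset.
#' @export
fit_instrumental_forest <- function(sample, outcome, covariates = NULL,
                                    params = forest_params(),
                                    seed = params$seed) {
  stopifnot(inherits(sample, "hf_sample"))
  ycol <- resolve_outcome(sample, outcome)
  X <- covariate_matrix(sample, covariates)
  fit <- instrumental_forest(
    X, sample[[ycol]], D = sample$D, Z = sample$Z,
    weights = sample$weight, clusters = sample$household_id,
    params = params, seed = seed)
  fit$sample <- sample[fit$kept, , drop = FALSE]
  attr(fit$sample, "covariates") <- attr(sample, "covariates")
  attr(fit$sample, "outcomes") <- attr(sample, "outcomes")
  fit$outcome <- ycol
  fit$treatment <- "D (instrumented by Z)"
  fit
}
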