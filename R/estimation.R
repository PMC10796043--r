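#' Doubly robust per-person scores
#'
#' Assembles the augmented inverse-probability-weighted (AIPW) score for each
#' person,
#' `gamma_i = m(X_i,1) - m(X_i,0) + (Y_i - m(X_i,Z_i)) (Z_i - e(X_i)) / (e(X_i)(1 - e(X_i)))`,
#' where the arm-specific means come from the marginal-mean identity
#' `m(x,1) = m(x) + (1 - e(x)) tau(x)` and `m(x,0) = m(x) - e(x) tau(x)`.
#' The weighted mean of these scores estimates the average treatment effect
#' with double robustness: it stays consistent when either the propensity or
#' the outcome model is misspecified.
#'
#' @param object A fitted [causal_forest()]; its out-of-bag nuisances and
#'   CATEs are used.  Rows with a missing out-of-bag CATE are dropped with a
#'   message.
#' @param ... Unused.
#' @return An object of class `"aipw_scores"`: a data frame with columns
#'   `gamma`, `weight`, `household`, and attributes `outcome` and
#'   `n_dropped`.
#' @seealso [compute_aipw_scores()] for the array-level constructor,
#'   [average_effect()], [group_average_effect()], [late_effect()]
#' @export
aipw_scores <- function(object, ...) {
  stopifnot(inherits(object, "causal_forest"))
  if (inherits(object, "instrumental_forest")) {
    stop(paste("AIPW scores are defined for causal forests;",
               "for instrumental analyses combine the outcome and",
               "first-stage score sets with late_effect()"), call. = FALSE)
  }
  keep <- !is.na(object$predictions)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("dropping %d row(s) without out-of-bag CATE", n_dropped))
  }
  scores <- compute_aipw_scores(
    Y = object$Y[keep], Z = object$Z[keep],
    m_hat = object$nuisance$m_hat[keep],
    e_hat = object$nuisance$e_hat[keep],
    tau_hat = object$predictions[keep],
    weights = object$weights[keep],
    households = object$clusters[keep],
    outcome = object$outcome %||% "Y")
  attr(scores, "n_dropped") <- n_dropped
  scores
}

#' @rdname aipw_scores
#' @param Y,Z Outcome and binary treatment vectors.
#' @param m_hat,e_hat,tau_hat Nuisance estimates aligned with `Y`: marginal
#'   mean, propensity (clamped internally to \[0.01, 0.99\]) and CATE.
#' @param weights Positive survey weights.
#' @param households Household (cluster) identifiers.
#' @param outcome Label carried through to results.
#' @export
compute_aipw_scores <- function(Y, Z, m_hat, e_hat, tau_hat,
                                weights = NULL, households = NULL,
                                outcome = "Y") {
  n <- length(Y)
  stopifnot(length(Z) == n, length(m_hat) == n, length(e_hat) == n,
            length(tau_hat) == n)
  weights <- weights %||% rep(1, n)
  households <- households %||% seq_len(n)
  e <- clamp(e_hat, 0.01, 0.99)
  m1 <- m_hat + (1 - e) * tau_hat
  m0 <- m_hat - e * tau_hat
  m_obs <- ifelse(Z == 1, m1, m0)
  gamma <- (m1 - m0) + (Y - m_obs) * (Z - e) / (e * (1 - e))
  if (any(!is.finite(gamma))) {
    stop("non-finite AIPW scores; check the nuisance inputs", call. = FALSE)
  }
  structure(
    data.frame(gamma = gamma, weight = weights, household = households),
    outcome = outcome, n_dropped = 0L,
    class = c("aipw_scores", "data.frame"))
}

#' Survey-weighted, cluster-robust average treatment effect
#'
#' Averages AIPW scores with survey weights and computes the
#' household-cluster-robust sandwich standard error: with household residual
#' sums `u_h = sum_{i in h} w_i (gamma_i - estimate)`,
#' `SE = sqrt(sum_h u_h^2) / sum_i w_i`, and the 95% interval is
#' `estimate +/- 1.96 SE`.
#'
#' @param scores An [aipw_scores()] object.
#' @param label Subgroup label attached to the estimate.
#' @return An object of class `"effect_estimate"`.
#' @export
average_effect <- function(scores, label = "overall") {
  stopifnot(inherits(scores, "aipw_scores"))
  if (nrow(scores) == 0) stop("empty score set", call. = FALSE)
  n_households <- length(unique(scores$household))
  if (n_households < 2) {
    stop("cluster-robust SE undefined with a single household",
         call. = FALSE)
  }
  W <- sum(scores$weight)
  est <- sum(scores$weight * scores$gamma) / W
  u_h <- household_sums(scores$weight * (scores$gamma - est),
                        scores$household)
  se <- sqrt(sum(u_h^2)) / W
  structure(
    list(estimate = est, se = se,
         ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
         n_persons = nrow(scores), n_households = n_households,
         sum_weight = W, label = label, outcome = attr(scores, "outcome")),
    class = "effect_estimate")
}

#' Subgroup (group average) treatment effect
#'
#' Restricts the AIPW score average to a prespecified subgroup.  Because the
#' estimator is a weighted mean of fixed per-person scores, subgroup
#' estimates over any partition recombine (share-weighted) to the overall
#' estimate exactly.
#'
#' @param scores An [aipw_scores()] object.
#' @param mask Logical mask aligned with the score rows.
#' @param label Subgroup name.
#' @return An `"effect_estimate"` for the subgroup.
#' @export
group_average_effect <- function(scores, mask, label = "subgroup") {
  stopifnot(inherits(scores, "aipw_scores"), length(mask) == nrow(scores))
  if (!any(mask)) {
    stop(sprintf("subgroup '%s' is empty", label), call. = FALSE)
  }
  sub <- scores[mask, , drop = FALSE]
  attr(sub, "outcome") <- attr(scores, "outcome")
  class(sub) <- c("aipw_scores", "data.frame")
  average_effect(sub, label = label)
}

#' Local average treatment effect among compliers
#'
#' Ratio of the intent-to-treat score average for the outcome to the
#' first-stage score average for realized treatment, with a delta-method
#' standard error built from the household-clustered covariance of the
#' paired score sums.
#'
#' @param scores_y AIPW scores of the outcome (effect of the instrument).
#' @param scores_d AIPW scores of realized treatment (first stage), aligned
#'   row-for-row with `scores_y`.
#' @param label Subgroup label.
#' @return An `"effect_estimate"` for the complier effect.
#' @export
late_effect <- function(scores_y, scores_d, label = "overall") {
  stopifnot(inherits(scores_y, "aipw_scores"),
            inherits(scores_d, "aipw_scores"))
  if (nrow(scores_y) != nrow(scores_d) ||
      !all(scores_y$household == scores_d$household)) {
    stop("outcome and first-stage scores are not aligned", call. = FALSE)
  }
  n_households <- length(unique(scores_y$household))
  if (n_households < 2) {
    stop("cluster-robust SE undefined with a single household",
         call. = FALSE)
  }
  W <- sum(scores_y$weight)
  num <- sum(scores_y$weight * scores_y$gamma) / W
  den <- sum(scores_d$weight * scores_d$gamma) / W
  if (abs(den) < 1e-6) {
    stop("weak instrument: first-stage effect is numerically zero",
         call. = FALSE)
  }
  est <- num / den
  u_h <- household_sums(scores_y$weight * (scores_y$gamma - num),
                        scores_y$household)
  v_h <- household_sums(scores_d$weight * (scores_d$gamma - den),
                        scores_d$household)
  var_num <- sum(u_h^2) / W^2
  var_den <- sum(v_h^2) / W^2
  cov_nd <- sum(u_h * v_h) / W^2
  se <- sqrt(pmax(
    (var_num - 2 * est * cov_nd + est^2 * var_den) / den^2, 0))
  structure(
    list(estimate = est, se = se,
         ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
         n_persons = nrow(scores_y), n_households = n_households,
         label = label, outcome = attr(scores_y, "outcome")),
    class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s [%s]: %.4g (95%% CI %.4g to %.4g), SE %.4g\n",
              x$outcome %||% "effect", x$label, x$estimate, x$ci_low,
              x$ci_high, x$se))
  cat(sprintf("  n = %d persons in %d households\n", x$n_persons,
              x$n_households))
  invisible(x)
}

#' Standardized difference between two groups
#'
#' Scale-free balance diagnostic: `|mean_1 - mean_0| / sqrt((v_1 + v_0)/2)`,
#' with `p(1-p)` variances for binary variables and survey-weighted moments
#' when weights are supplied.
#'
#' @param values Numeric (binary or continuous) variable.
#' @param group Binary group indicator (0/1 or logical).
#' @param weights Optional positive weights.
#' @param binary Force binary treatment of `values`; default auto-detects
#'   values confined to \{0, 1\}.
#' @return The standardized difference (a nonnegative scalar).
#' @export
standardized_difference <- function(values, group, weights = NULL,
                                    binary = NULL) {
  group <- as.integer(as.logical(group))
  weights <- weights %||% rep(1, length(values))
  if (!any(group == 1) || !any(group == 0)) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  binary <- binary %||% all(values %in% c(0, 1))
  moments <- function(g) {
    idx <- group == g
    m <- weighted_mean(values[idx], weights[idx])
    v <- if (binary) m * (1 - m) else weighted_var(values[idx], weights[idx])
    c(m, v)
  }
  m1 <- moments(1L)
  m0 <- moments(0L)
  denom <- sqrt((m1[2] + m0[2]) / 2)
  if (denom == 0) return(0)
  abs(m1[1] - m0[1]) / denom
}

#' Covariate balance table
#'
#' Standardized differences of every covariate between the two arms of a
#' binary grouping column, the machine-readable analogue of a baseline
#' characteristics table.
#'
#' @param sample An `hf_sample`.
#' @param by Grouping column (default the lottery indicator `Z`).
#' @param weighted Use survey weights (default `TRUE`).
#' @return Data frame with columns `covariate`, `mean_0`, `mean_1`,
#'   `std_diff`.
#' @export
balance_table <- function(sample, by = "Z", weighted = TRUE) {
  stopifnot(inherits(sample, "hf_sample"))
  X <- covariate_matrix(sample)
  g <- sample[[by]]
  w <- if (weighted) sample$weight else rep(1, nrow(sample))
  rows <- lapply(colnames(X), function(nm) {
    v <- X[, nm]
    data.frame(
      covariate = nm,
      mean_0 = weighted_mean(v[g == 0], w[g == 0]),
      mean_1 = weighted_mean(v[g == 1], w[g == 1]),
      std_diff = standardized_difference(v, g, w))
  })
  do.call(rbind, rows)
}
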