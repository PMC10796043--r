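#' Omnibus calibration test for effect heterogeneity
#'
#' Best-linear-predictor calibration of the forest: the centered outcome
#' `Y - m_hat` is regressed (survey-weighted, no intercept) on the two
#' constructed regressors `(Z - e_hat) * tau_bar` and
#' `(Z - e_hat) * (tau_oob - tau_bar)`, where `tau_bar` is the weighted mean
#' out-of-bag CATE.  The first coefficient (`alpha`) calibrates the mean
#' forest prediction -- values near one indicate the average effect is well
#' captured; the second (`beta`) calibrates the differential prediction --
#' under real heterogeneity captured by the forest, beta is near one, and a
#' one-sided test of `beta > 0` is the omnibus heterogeneity test.
#' Standard errors are household-cluster-robust.
#'
#' @param object A fitted [causal_forest()].
#' @return An object of class `"calibration_result"` with `alpha`, `beta`,
#'   their cluster-robust standard errors, the one-sided `p_beta`, and
#'   `beta_estimable` (`FALSE` when the out-of-bag CATEs are constant, in
#'   which case `beta` is flagged not estimable and only `alpha` is fit).
#' @export
calibration_test <- function(object) {
  stopifnot(inherits(object, "causal_forest"))
  keep <- !is.na(object$predictions)
  tau <- object$predictions[keep]
  w <- object$weights[keep]
  yres <- object$residuals$y_res[keep]
  zres <- object$residuals$z_res[keep]
  hh <- object$clusters[keep]

  tau_bar <- weighted_mean(tau, w)
  beta_estimable <- weighted_var(tau, w) > 1e-12
  Xmat <- if (beta_estimable) {
    cbind(mean_pred = zres * tau_bar, diff_pred = zres * (tau - tau_bar))
  } else {
    cbind(mean_pred = zres * tau_bar)
  }
  fit <- cluster_wls(Xmat, yres, w, hh)
  alpha <- fit$coef["mean_pred"]
  se_alpha <- fit$se["mean_pred"]
  if (beta_estimable) {
    beta <- fit$coef["diff_pred"]
    se_beta <- fit$se["diff_pred"]
    p_beta <- stats::pnorm(beta / se_beta, lower.tail = FALSE)
  } else {
    beta <- NA_real_
    se_beta <- NA_real_
    p_beta <- NA_real_
  }
  structure(
    list(alpha = unname(alpha), beta = unname(beta),
         se_alpha = unname(se_alpha), se_beta = unname(se_beta),
         p_beta = unname(p_beta), beta_estimable = beta_estimable,
         n = length(tau)),
    class = "calibration_result")
}

# weighted least squares (no intercept) with household-cluster sandwich SEs
cluster_wls <- function(Xmat, y, w, households) {
  XtWX <- crossprod(Xmat, w * Xmat)
  bread <- solve(XtWX)
  coef <- drop(bread %*% crossprod(Xmat, w * y))
  names(coef) <- colnames(Xmat)
  resid <- y - drop(Xmat %*% coef)
  scores <- (w * resid) * Xmat
  g <- rowsum(scores, group = households, reorder = TRUE)
  meat <- crossprod(as.matrix(g))
  V <- bread %*% meat %*% bread
  list(coef = coef,
       se = stats::setNames(sqrt(pmax(diag(V), 0)), colnames(Xmat)),
       vcov = V)
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Calibration of forest effect predictions:\n")
  cat(sprintf("  mean prediction (alpha): %.4g (SE %.4g)\n", x$alpha,
              x$se_alpha))
  if (x$beta_estimable) {
    cat(sprintf(
      "  differential prediction (beta): %.4g (SE %.4g), one-sided p = %.4g\n",
      x$beta, x$se_beta, x$p_beta))
  } else {
    cat("  differential prediction: not estimable (constant CATEs)\n")
  }
  invisible(x)
}

#' Cross-fitted omnibus calibration test
#'
#' Household-level two-fold cross-fitted variant of [calibration_test()].
#' The plug-in construction reuses each observation both inside the
#' out-of-bag CATEs (through other observations' kernel averages and the
#' estimated mean CATE) and as a regression row, which makes it
#' conservative when the true effect is exactly homogeneous.  Here the
#' regressors for each fold -- centered treatment, CATE predictions and
#' their fold mean -- are built entirely from a forest fit on the other
#' fold, removing the coupling; the stacked weighted regression then has
#' nominal operating characteristics for the one-sided heterogeneity test.
#'
#' @param sample An `hf_sample`.
#' @param outcome Outcome name or index.
#' @param treatment Treatment column (default `"Z"`).
#' @param params A [forest_params()] for the half-sample forests.
#' @param seed Integer seed (fold assignment and forest fits).
#' @return A `"calibration_result"`, as for [calibration_test()].
#' @export
calibration_test_crossfit <- function(sample, outcome, treatment = "Z",
                                      params = forest_params(),
                                      seed = 1L) {
  stopifnot(inherits(sample, "hf_sample"))
  households <- unique(sample$household_id)
  fold_a <- with_substream(seed, "calibration_folds", {
    sample(households, floor(length(households) / 2))
  })
  in_a <- sample$household_id %in% fold_a
  rows <- list()
  for (f in 1:2) {
    eval_rows <- if (f == 1) in_a else !in_a
    fit_half <- sample[!eval_rows, , drop = FALSE]
    attr(fit_half, "covariates") <- attr(sample, "covariates")
    attr(fit_half, "outcomes") <- attr(sample, "outcomes")
    class(fit_half) <- c("hf_sample", "data.frame")
    fit <- suppressMessages(fit_causal_forest(
      fit_half, outcome, treatment, params = params,
      seed = hf_substream(seed, paste0("calibration_fit:", f))))
    ev <- sample[eval_rows, , drop = FALSE]
    Xe <- as.matrix(ev[, attr(sample, "covariates"), drop = FALSE])
    storage.mode(Xe) <- "double"
    m_hat <- as.numeric(predict(fit$m_forest, newdata = Xe))
    e_hat <- clamp(as.numeric(predict(fit$e_forest, newdata = Xe)),
                   0.01, 0.99)
    tau <- as.numeric(predict(fit, newdata = Xe))
    w <- ev$weight
    ycol <- resolve_outcome(sample, outcome)
    yres <- ev[[ycol]] - m_hat
    zres <- ev[[treatment]] - e_hat
    tau_bar <- weighted_mean(tau, w)
    rows[[f]] <- data.frame(
      yres = yres, c1 = zres * tau_bar, c2 = zres * (tau - tau_bar),
      w = w, hh = ev$household_id)
  }
  # each fold's regression is internally valid (its regressors are built
  # from the other fold only); the folds are dependent through their swapped
  # roles, so the one-sided p-values are combined by Bonferroni, which
  # bounds the level without modelling that dependence
  beta_estimable <- all(vapply(rows, function(d) stats::var(d$c2) > 1e-12,
                               logical(1)))
  fold_fit <- lapply(rows, function(d) {
    Xmat <- if (beta_estimable) {
      cbind(mean_pred = d$c1, diff_pred = d$c2)
    } else {
      cbind(mean_pred = d$c1)
    }
    cluster_wls(Xmat, d$yres, d$w, d$hh)
  })
  ivw <- function(coefs, ses) {
    v <- ses^2
    est <- sum(coefs / v) / sum(1 / v)
    c(est, sqrt(1 / sum(1 / v)))
  }
  a <- ivw(vapply(fold_fit, function(f) f$coef["mean_pred"], numeric(1)),
           vapply(fold_fit, function(f) f$se["mean_pred"], numeric(1)))
  if (beta_estimable) {
    bs <- vapply(fold_fit, function(f) f$coef["diff_pred"], numeric(1))
    bses <- vapply(fold_fit, function(f) f$se["diff_pred"], numeric(1))
    b <- ivw(bs, bses)
    p_fold <- stats::pnorm(bs / bses, lower.tail = FALSE)
    p_beta <- min(1, 2 * min(p_fold))
  } else {
    b <- c(NA_real_, NA_real_)
    p_beta <- NA_real_
  }
  structure(
    list(alpha = a[1], beta = b[1], se_alpha = a[2], se_beta = b[2],
         p_beta = p_beta, beta_estimable = beta_estimable,
         n = sum(vapply(rows, nrow, integer(1)))),
    class = "calibration_result")
}

#' Targeting operator characteristic curve
#'
#' For each treated fraction q, TOC(q) is the weighted mean AIPW score among
#' the top-q fraction of the population ranked by a priority score, minus
#' the overall weighted mean: it measures how much better than average the
#' prioritized group benefits.  The rank-weighted average treatment effect
#' (RATE) summarizes the curve by its integral over q (AUTOC weighting) or
#' by the q-weighted integral (Qini).  Priorities should come from a fitting
#' half disjoint from the evaluation scores (contract documented, not
#' enforced).
#'
#' @param scores An [aipw_scores()] object for the evaluation half.
#' @param priority Per-person ranking values aligned with `scores` (higher =
#'   treated first).  Ties are broken by stable order with a warning.
#' @param q_grid Treated fractions in (0, 1]; default 100 evenly spaced
#'   points ending at 1, where TOC(1) = 0 by construction.
#' @param method `"autoc"` (default) or `"qini"` rank weighting for the
#'   area statistic.
#' @return An object of class `"toc_curve"`: `q_grid`, `toc`, `rate`,
#'   `se_rate` (`NA` unless estimated by [rate_with_se()]).
#' @export
toc_curve <- function(scores, priority, q_grid = seq(0.01, 1, by = 0.01),
                      method = c("autoc", "qini")) {
  method <- match.arg(method)
  stopifnot(inherits(scores, "aipw_scores"),
            length(priority) == nrow(scores))
  if (any(q_grid <= 0 | q_grid > 1)) {
    stop("q_grid values must lie in (0, 1]", call. = FALSE)
  }
  q_grid <- sort(q_grid)
  if (anyDuplicated(priority[!is.na(priority)])) {
    warning("tied priorities detected; cuts inside a tied block are prorated",
            call. = FALSE)
  }
  ord <- order(priority, decreasing = TRUE)
  g <- scores$gamma[ord]
  w <- scores$weight[ord]
  pr <- priority[ord]
  # tied priorities carry no ranking information: prorate a cut inside a
  # tied block by replacing each member's score with the block mean
  blocks <- cumsum(!duplicated(pr))
  g <- stats::ave(w * g, blocks, FUN = sum) / stats::ave(w, blocks,
                                                         FUN = sum)
  W <- sum(w)
  overall <- sum(w * g) / W
  cw <- cumsum(w)
  cwg <- cumsum(w * g)
  # smallest prefix holding at least fraction q of the weight mass
  idx <- findInterval(q_grid * W - 1e-12, cw) + 1L
  idx <- pmin(idx, length(g))
  toc <- cwg[idx] / cw[idx] - overall
  rate_w <- if (method == "qini") q_grid else rep(1, length(q_grid))
  integrand <- rate_w * toc
  rate <- sum(diff(q_grid) * (utils::head(integrand, -1) +
                                utils::tail(integrand, -1)) / 2)
  structure(
    list(q_grid = q_grid, toc = toc, rate = rate, se_rate = NA_real_,
         method = method, overall = overall),
    class = "toc_curve")
}

#' @export
print.toc_curve <- function(x, ...) {
  cat(sprintf("TOC curve (%s): rate = %.4g%s over %d grid points\n",
              x$method, x$rate,
              if (is.na(x$se_rate)) "" else sprintf(" (SE %.4g)", x$se_rate),
              length(x$q_grid)))
  invisible(x)
}

#' @export
plot.toc_curve <- function(x, ...) {
  graphics::plot(x$q_grid, x$toc, type = "l",
                 xlab = "treated fraction q", ylab = "TOC(q)",
                 main = sprintf("Targeting operator characteristic (rate %.3g)",
                                x$rate), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Rank-weighted average treatment effect with a split-based SE
#'
#' Repeats a household-level half-split protocol: fit a causal forest on a
#' random half of the households, rank the held-out half by its predicted
#' CATEs, evaluate the TOC/RATE on the held-out half's own AIPW scores
#' (from a forest fit on that half), and average across splits.  The
#' reported standard error is the empirical standard error of the mean rate
#' across splits.
#'
#' @param sample An `hf_sample`.
#' @param outcome Outcome name or index.
#' @param params A [forest_params()] for the half-sample forests.
#' @param n_half_splits Number of repeated half-splits (at least 2).
#' @param seed Integer seed.
#' @param method `"autoc"` or `"qini"`.
#' @return A `"toc_curve"` whose `rate` is the mean across splits, with
#'   `se_rate` filled in and per-split rates in `$rates`.
#' @export
rate_with_se <- function(sample, outcome, params = forest_params(),
                         n_half_splits = 5L, seed = 1L,
                         method = c("autoc", "qini")) {
  method <- match.arg(method)
  stopifnot(inherits(sample, "hf_sample"))
  if (n_half_splits < 2L) {
    stop("n_half_splits must be at least 2", call. = FALSE)
  }
  households <- unique(sample$household_id)
  rates <- numeric(n_half_splits)
  last_curve <- NULL
  for (s in seq_len(n_half_splits)) {
    fit_hh <- with_substream(seed, paste0("rate_split:", s), {
      sample(households, floor(length(households) / 2))
    })
    in_fit <- sample$household_id %in% fit_hh
    fit_half <- sample[in_fit, , drop = FALSE]
    eval_half <- sample[!in_fit, , drop = FALSE]
    for (half in c("fit_half", "eval_half")) {
      h <- get(half)
      attr(h, "covariates") <- attr(sample, "covariates")
      attr(h, "outcomes") <- attr(sample, "outcomes")
      class(h) <- c("hf_sample", "data.frame")
      assign(half, h)
    }
    f_fit <- fit_causal_forest(fit_half, outcome, params = params,
                               seed = hf_substream(seed, paste0("rate_fit:", s)))
    f_eval <- fit_causal_forest(eval_half, outcome, params = params,
                                seed = hf_substream(seed, paste0("rate_eval:", s)))
    priority <- as.numeric(predict(f_fit,
                                   newdata = covariate_matrix(f_eval$sample)))
    sc <- suppressMessages(aipw_scores(f_eval))
    keep <- !is.na(f_eval$predictions)
    curve <- suppressWarnings(toc_curve(sc, priority[keep], method = method))
    rates[s] <- curve$rate
    last_curve <- curve
  }
  out <- last_curve
  out$rate <- mean(rates)
  out$se_rate <- stats::sd(rates) / sqrt(n_half_splits)
  out$rates <- rates
  out
}
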