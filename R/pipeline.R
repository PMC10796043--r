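#' Analysis configuration
#'
#' Bundles everything [run_analysis()] needs: outcomes, forest
#' hyperparameters, the tuning budget, the covariate retention threshold of
#' the two-stage fit, and optional analysis passes.
#'
#' @param outcomes Outcome names (default: all outcomes of the sample).
#' @param params Base [forest_params()].
#' @param tuning [tuning_budget()]; a budget of zero candidate draws (the
#'   default) skips tuning and uses `params` as is.
#' @param retention_threshold Stage-two covariates are retained when their
#'   importance exceeds this fraction of the mean importance (default 0.20).
#' @param include_iv Also run the instrumental (complier-effect) pass.
#' @param include_uptake Also run the three-stage uptake decomposition.
#' @param seed Root seed for the whole analysis.
#' @return An object of class `"analysis_config"`.
#' @export
analysis_config <- function(outcomes = NULL,
                            params = forest_params(),
                            tuning = tuning_budget(),
                            retention_threshold = 0.20,
                            include_iv = FALSE,
                            include_uptake = FALSE,
                            seed = 1L) {
  if (retention_threshold <= 0 || retention_threshold >= 1) {
    stop("retention_threshold must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(outcomes = outcomes, params = params, tuning = tuning,
         retention_threshold = retention_threshold,
         include_iv = include_iv, include_uptake = include_uptake,
         seed = as.integer(seed)),
    class = "analysis_config")
}

#' @rdname analysis_config
#' @param n_candidate_draws Random hyperparameter vectors evaluated (0 =
#'   skip tuning).  Production-scale protocols use thousands of draws with
#'   hundreds of trees per tuning forest; the desk-scale defaults are 50
#'   draws of 200-tree forests.
#' @param trees_per_tuning_forest Trees in each candidate-evaluation forest.
#' @param n_tuning_forests Documented production-protocol field (number of
#'   forests behind the tuning model); candidate evaluation here fits one
#'   small forest per draw.
#' @export
tuning_budget <- function(n_candidate_draws = 0L,
                          trees_per_tuning_forest = 200L,
                          n_tuning_forests = 1000L) {
  stopifnot(n_candidate_draws >= 0, trees_per_tuning_forest >= 1)
  list(n_candidate_draws = as.integer(n_candidate_draws),
       trees_per_tuning_forest = as.integer(trees_per_tuning_forest),
       n_tuning_forests = as.integer(n_tuning_forests))
}

#' Random-search hyperparameter tuning by the R-loss
#'
#' Draws random hyperparameter vectors (sample fraction, honesty fraction,
#' mtry, minimum node size, imbalance parameters) from documented ranges,
#' scores each candidate -- and the defaults -- by the survey-weighted
#' out-of-bag R-loss `mean(0.5 * (Y - m_hat - tau_oob (Z - e_hat))^2)` of a
#' small causal forest, and returns the minimizer (with the base tree count
#' restored).  A budget of zero draws returns `params` unchanged.
#'
#' @param sample An `hf_sample`.
#' @param outcome Outcome name or index.
#' @param treatment Treatment column (default `"Z"`).
#' @param budget A [tuning_budget()].
#' @param params Base [forest_params()] (also the fallback candidate).
#' @param seed Integer seed.
#' @return A [forest_params()]; attribute `"tuning"` holds the evaluated
#'   candidate table with R-losses.
#' @export
tune_hyperparameters <- function(sample, outcome, treatment = "Z",
                                 budget = tuning_budget(50L),
                                 params = forest_params(), seed = 1L) {
  stopifnot(inherits(sample, "hf_sample"))
  if (budget$n_candidate_draws == 0L) {
    return(params)
  }
  p <- length(attr(sample, "covariates"))
  draws <- with_substream(seed, "tuning_draws", {
    data.frame(
      sample_fraction = stats::runif(budget$n_candidate_draws, 0.25, 0.70),
      honesty_fraction = stats::runif(budget$n_candidate_draws, 0.40, 0.70),
      mtry = sample.int(p, budget$n_candidate_draws, replace = TRUE),
      min_node_size = round(exp(stats::runif(budget$n_candidate_draws,
                                             log(5), log(50)))),
      alpha_imbalance = stats::runif(budget$n_candidate_draws, 0.01, 0.25),
      imbalance_penalty = stats::runif(budget$n_candidate_draws, 0, 2))
  })
  defaults_row <- data.frame(
    sample_fraction = params$sample_fraction,
    honesty_fraction = params$honesty_fraction,
    mtry = params$mtry %||% ceiling(sqrt(p)),
    min_node_size = params$min_node_size,
    alpha_imbalance = params$alpha_imbalance,
    imbalance_penalty = params$imbalance_penalty)
  draws <- rbind(defaults_row, draws)
  rloss <- vapply(seq_len(nrow(draws)), function(k) {
    cand <- forest_params(
      n_trees = budget$trees_per_tuning_forest,
      sample_fraction = draws$sample_fraction[k],
      honesty_fraction = draws$honesty_fraction[k],
      mtry = draws$mtry[k],
      min_node_size = draws$min_node_size[k],
      alpha_imbalance = draws$alpha_imbalance[k],
      imbalance_penalty = draws$imbalance_penalty[k])
    fit <- suppressMessages(suppressWarnings(fit_causal_forest(
      sample, outcome, treatment, params = cand,
      seed = hf_substream(seed, paste0("tuning_fit:", k)))))
    r_loss(fit)
  }, numeric(1))
  best <- which.min(rloss)
  draws$rloss <- rloss
  out <- forest_params(
    n_trees = params$n_trees,
    sample_fraction = draws$sample_fraction[best],
    honesty_fraction = draws$honesty_fraction[best],
    mtry = draws$mtry[best],
    min_node_size = draws$min_node_size[best],
    alpha_imbalance = draws$alpha_imbalance[best],
    imbalance_penalty = draws$imbalance_penalty[best],
    seed = params$seed)
  attr(out, "tuning") <- draws
  out
}

#' @rdname tune_hyperparameters
#' @param fit A fitted [causal_forest()].
#' @export
r_loss <- function(fit) {
  keep <- !is.na(fit$predictions)
  res <- fit$residuals$y_res[keep] -
    fit$predictions[keep] * fit$residuals$z_res[keep]
  weighted_mean(0.5 * res^2, fit$weights[keep])
}

#' Covariate retention rule of the two-stage fit
#'
#' @param importance Named importance vector (e.g. from
#'   [variable_importance()]).
#' @param threshold Retain covariates whose importance exceeds `threshold`
#'   times the mean importance (default 0.20).
#' @return Character vector of retained covariate names.
#' @export
retain_covariates <- function(importance, threshold = 0.20) {
  keep <- names(importance)[importance > threshold * mean(importance)]
  if (length(keep) == 0) {
    stop("no covariates retained; importance vector looks degenerate",
         call. = FALSE)
  }
  keep
}

#' Two-stage covariate-selected causal forest
#'
#' Fits a first-stage forest on all covariates, retains those whose
#' depth-weighted split importance exceeds a fraction of the mean
#' importance, and refits (nuisances included) on the retained set.
#'
#' @inheritParams tune_hyperparameters
#' @param retention_threshold Fraction of mean importance (default 0.20).
#' @return List with `forest` (the stage-two fit), `retained`,
#'   `importance` (stage-one scores) and `stage1` (the stage-one fit).
#' @export
two_stage_fit <- function(sample, outcome, treatment = "Z",
                          params = forest_params(),
                          retention_threshold = 0.20, seed = 1L) {
  if (length(attr(sample, "covariates")) < 2) {
    stop("two-stage fitting needs at least 2 covariates", call. = FALSE)
  }
  stage1 <- fit_causal_forest(sample, outcome, treatment, params = params,
                              seed = hf_substream(seed, "stage1"))
  importance <- variable_importance(stage1)
  retained <- retain_covariates(importance, retention_threshold)
  stage2 <- fit_causal_forest(sample, outcome, treatment,
                              covariates = retained, params = params,
                              seed = hf_substream(seed, "stage2"))
  list(forest = stage2, retained = retained, importance = importance,
       stage1 = stage1)
}

effect_row <- function(est, outcome, analysis) {
  data.frame(
    outcome = outcome, analysis = analysis, subgroup = est$label,
    estimate = est$estimate, se = est$se,
    ci_low = est$ci_low, ci_high = est$ci_high,
    p_value = 2 * stats::pnorm(-abs(est$estimate) / est$se),
    n_persons = est$n_persons, n_households = est$n_households,
    sum_weight = est$sum_weight %||% NA_real_,
    stringsAsFactors = FALSE)
}

#' Subgroup effect table for a fitted forest
#'
#' Computes the AIPW overall effect and every subgroup effect for the
#' prespecified subgroup system of the forest's analysis sample.
#'
#' @param forest A [fit_causal_forest()] result (carries its sample).
#' @param subgroups Optional named list of masks over the forest's analysis
#'   sample; default [make_subgroups()].
#' @param analysis Label for the analysis column (default `"itt"`).
#' @return Data frame with one row per subgroup (overall first).
#' @export
gate_table <- function(forest, subgroups = NULL, analysis = "itt") {
  stopifnot(!is.null(forest$sample))
  scores <- suppressMessages(aipw_scores(forest))
  keep <- !is.na(forest$predictions)
  masks <- subgroups %||% make_subgroups(forest$sample)
  rows <- lapply(names(masks), function(nm) {
    effect_row(group_average_effect(scores, masks[[nm]][keep], label = nm),
               forest$outcome, analysis)
  })
  do.call(rbind, rows)
}

#' Three-stage insurance-uptake decomposition
#'
#' Estimates three intent-to-treat causal forests whose outcomes are the
#' consecutive stages of the enrollment funnel -- applying for coverage,
#' having the application approved, and enrolling -- and tabulates subgroup
#' effects per stage together with the stage-to-stage drops in the effect of
#' lottery selection.
#'
#' @inheritParams two_stage_fit
#' @param subgroups Optional named mask list; default [make_subgroups()].
#' @return An object of class `"stage_results"`: per-stage forests and
#'   subgroup tables, plus `stage_gaps` with the application-to-approval and
#'   approval-to-uptake intent-to-treat differences.
#' @export
uptake_decomposition <- function(sample, params = forest_params(),
                                 seed = 1L, subgroups = NULL) {
  stopifnot(inherits(sample, "hf_sample"))
  if (all(is.na(sample$applied))) {
    stop("uptake decomposition requires the funnel flags", call. = FALSE)
  }
  validate_sample(sample)
  stages <- c(applied = "applied", approved = "approved", uptake = "D")
  forests <- list()
  tables <- list()
  for (st in names(stages)) {
    forests[[st]] <- suppressMessages(fit_causal_forest(
      sample, outcome = stages[[st]], treatment = "Z", params = params,
      seed = hf_substream(seed, paste0("stage:", st))))
    masks <- if (is.null(subgroups)) {
      make_subgroups(forests[[st]]$sample)
    } else {
      lapply(subgroups, function(m) m[forests[[st]]$kept])
    }
    tables[[st]] <- gate_table(forests[[st]], subgroups = masks,
                               analysis = paste0("itt_", st))
  }
  gaps <- data.frame(
    subgroup = tables$applied$subgroup,
    applied_itt = tables$applied$estimate,
    approved_itt = tables$approved$estimate[
      match(tables$applied$subgroup, tables$approved$subgroup)],
    uptake_itt = tables$uptake$estimate[
      match(tables$applied$subgroup, tables$uptake$subgroup)],
    stringsAsFactors = FALSE)
  gaps$gap_application_approval <- gaps$applied_itt - gaps$approved_itt
  gaps$gap_approval_uptake <- gaps$approved_itt - gaps$uptake_itt
  structure(list(forests = forests, tables = tables, stage_gaps = gaps),
            class = "stage_results")
}

#' @export
print.stage_results <- function(x, ...) {
  ov <- x$stage_gaps[x$stage_gaps$subgroup == "overall", ]
  cat("Three-stage uptake decomposition (intent-to-treat effects):\n")
  cat(sprintf("  application %.3f -> approval %.3f -> uptake %.3f\n",
              ov$applied_itt, ov$approved_itt, ov$uptake_itt))
  cat(sprintf("  stage gaps: %.3f (application to approval), %.3f (approval to uptake)\n",
              ov$gap_application_approval, ov$gap_approval_uptake))
  invisible(x)
}

#' Run the full heterogeneity analysis
#'
#' For each outcome: optional hyperparameter tuning, a two-stage
#' covariate-selected intent-to-treat causal forest, the AIPW overall effect
#' and all prespecified subgroup effects, and the omnibus calibration test.
#' Optionally adds the instrumental (complier-effect) pass and the
#' three-stage uptake decomposition, plus the covariate balance table.
#' Fully deterministic given the configuration seed.
#'
#' @param sample An `hf_sample`.
#' @param config An [analysis_config()].
#' @return An object of class `"hf_report"` with data frames `ate_gate`,
#'   `diagnostics`, `balance`, optional `iv` and `uptake`, and a `manifest`
#'   list (seed, per-outcome parameters and retained covariates, drop
#'   counts, and the count of intent-to-treat tests that would survive a
#'   Bonferroni correction -- reported for documentation only, no
#'   correction is applied).
#' @export
run_analysis <- function(sample, config = analysis_config()) {
  stopifnot(inherits(sample, "hf_sample"))
  validate_sample(sample)
  outcomes <- config$outcomes %||% attr(sample, "outcomes")
  seed <- config$seed
  ate_gate <- list()
  diagnostics <- list()
  iv_rows <- list()
  manifest <- list(seed = seed, outcomes = outcomes,
                   params = list(), retained = list(), dropped = list())

  for (oc in outcomes) {
    params_oc <- if (config$tuning$n_candidate_draws > 0) {
      tune_hyperparameters(sample, oc, budget = config$tuning,
                           params = config$params,
                           seed = hf_substream(seed, paste0("tune:", oc)))
    } else {
      config$params
    }
    tsf <- suppressMessages(two_stage_fit(
      sample, oc, params = params_oc,
      retention_threshold = config$retention_threshold,
      seed = hf_substream(seed, paste0("fit:", oc))))
    forest <- tsf$forest
    ate_gate[[oc]] <- gate_table(forest)
    cal <- calibration_test(forest)
    diagnostics[[oc]] <- data.frame(
      outcome = forest$outcome, alpha = cal$alpha, se_alpha = cal$se_alpha,
      beta = cal$beta, se_beta = cal$se_beta, p_beta = cal$p_beta,
      stringsAsFactors = FALSE)
    manifest$params[[oc]] <- unclass(params_oc)
    manifest$retained[[oc]] <- tsf$retained
    manifest$dropped[[oc]] <- forest$n_dropped

    if (config$include_iv) {
      iv_rows[[oc]] <- iv_gate_table(sample, oc, tsf$retained, params_oc,
                                     seed)
    }
  }
  ate_gate <- do.call(rbind, ate_gate)
  rownames(ate_gate) <- NULL
  diagnostics <- do.call(rbind, diagnostics)
  rownames(diagnostics) <- NULL

  # documentation-only multiplicity note: no correction is applied
  n_tests <- nrow(ate_gate)
  manifest$n_bonferroni_significant <-
    sum(ate_gate$p_value < 0.05 / n_tests)

  report <- list(
    ate_gate = ate_gate,
    diagnostics = diagnostics,
    balance = balance_table(sample),
    iv = if (length(iv_rows) > 0) {
      out <- do.call(rbind, iv_rows); rownames(out) <- NULL; out
    } else {
      NULL
    },
    uptake = if (config$include_uptake) {
      uptake_decomposition(sample, params = config$params,
                           seed = hf_substream(seed, "uptake"))
    } else {
      NULL
    },
    manifest = manifest)
  class(report) <- "hf_report"
  report
}

# complier-effect (LATE) subgroup table: ratio of outcome to first-stage
# AIPW score means on the persons common to both causal-forest fits
iv_gate_table <- function(sample, outcome, covariates, params, seed) {
  fy <- suppressMessages(fit_causal_forest(
    sample, outcome, covariates = covariates, params = params,
    seed = hf_substream(seed, paste0("iv_y:", outcome))))
  fd <- suppressMessages(fit_causal_forest(
    sample, "D", covariates = covariates, params = params,
    seed = hf_substream(seed, paste0("iv_d:", outcome))))
  sy <- suppressMessages(aipw_scores(fy))
  sd_ <- suppressMessages(aipw_scores(fd))
  py <- fy$sample$person_id[!is.na(fy$predictions)]
  pd <- fd$sample$person_id[!is.na(fd$predictions)]
  common <- intersect(py, pd)
  sy <- sy[match(common, py), , drop = FALSE]
  sd_ <- sd_[match(common, pd), , drop = FALSE]
  for (s in c("sy", "sd_")) {
    v <- get(s)
    class(v) <- c("aipw_scores", "data.frame")
    attr(v, "outcome") <- if (s == "sy") fy$outcome else "D"
    assign(s, v)
  }
  sub_sample <- fy$sample[match(common, fy$sample$person_id), , drop = FALSE]
  class(sub_sample) <- c("hf_sample", "data.frame")
  masks <- make_subgroups(sub_sample)
  rows <- lapply(names(masks), function(nm) {
    m <- masks[[nm]]
    if (!any(m)) return(NULL)
    yk <- sy[m, , drop = FALSE]
    dk <- sd_[m, , drop = FALSE]
    for (s in c("yk", "dk")) {
      v <- get(s)
      class(v) <- c("aipw_scores", "data.frame")
      attr(v, "outcome") <- fy$outcome
      assign(s, v)
    }
    effect_row(late_effect(yk, dk, label = nm), fy$outcome, "iv")
  })
  do.call(rbind, rows)
}

#' @export
print.hf_report <- function(x, ...) {
  cat(sprintf("Heterogeneity analysis report: %d outcomes x %d subgroups\n",
              length(unique(x$ate_gate$outcome)),
              length(unique(x$ate_gate$subgroup))))
  ov <- x$ate_gate[x$ate_gate$subgroup == "overall", ]
  for (k in seq_len(nrow(ov))) {
    cat(sprintf("  %-22s ATE %8.4g (%.4g, %.4g)\n", ov$outcome[k],
                ov$estimate[k], ov$ci_low[k], ov$ci_high[k]))
  }
  if (!is.null(x$manifest$n_bonferroni_significant)) {
    cat(sprintf(
      "  (%d of %d intent-to-treat tests would survive Bonferroni; no correction applied)\n",
      x$manifest$n_bonferroni_significant, nrow(x$ate_gate)))
  }
  invisible(x)
}
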