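test_that("a null effect yields a near-zero doubly robust estimate", {
  cfg <- small_config(n_households = 800,
                      effect = list(type = "constant", value = 0))
  g <- generate_sample(cfg, seed = 13)
  fit <- suppressMessages(fit_causal_forest(g$sample, "y1",
                                            params = quick_params(200),
                                            seed = 1))
  est <- average_effect(suppressMessages(aipw_scores(fit)))
  expect_lt(abs(est$estimate), 3 * est$se)
})

test_that("a two-subgroup effect is recovered within the stated band", {
  cfg <- small_config(
    n_households = 3200,
    effect = list(type = "step", covariate = "white",
                  value_in = 3, value_out = 1))
  g <- generate_sample(cfg, seed = 17)
  fit <- suppressMessages(fit_causal_forest(
    g$sample, "y1", params = quick_params(300, mtry = 7), seed = 2))
  tau <- fit$predictions
  white <- fit$sample$white == 1
  keep <- !is.na(tau)
  expect_lt(abs(mean(tau[keep & white]) - 3), 0.3)
  expect_lt(abs(mean(tau[keep & !white]) - 1), 0.3)
})

test_that("kernel weights are a normalized nonnegative distribution and
           reproduce the prediction when plugged into the ratio estimator", {
  g <- generate_sample(small_config(n_households = 250), seed = 19)
  fit <- suppressMessages(fit_causal_forest(g$sample, "y1",
                                            params = quick_params(50),
                                            seed = 3))
  X <- fit$X
  for (i in c(1, 7, 30)) {
    aw <- alpha_weights(fit, X[i, ])
    expect_true(all(aw$alpha >= 0))
    expect_equal(sum(aw$alpha), 1, tolerance = 1e-8)
    # independent evaluation of the locally weighted ratio estimator
    num <- sum(aw$alpha * fit$weights * fit$residuals$y_res *
                 fit$residuals$z_res)
    den <- sum(aw$alpha * fit$weights * fit$residuals$z_res^2)
    expect_equal(as.numeric(predict(fit, newdata = X[i, , drop = FALSE])),
                 num / den, tolerance = 1e-10)
  }
})

test_that("a single unsplit tree predicts the root ratio estimator everywhere", {
  set.seed(20)
  n <- 120
  X <- matrix(1, n, 3)   # constant covariates: nothing to split on
  Z <- rbinom(n, 1, 0.5)
  z <- Z - 0.5
  y <- rnorm(n) + Z
  tree <- grow_single_tree(X, y, z, rep(1, n), Z, min_node_size = 2,
                           seed = 4)
  expect_equal(tree$flat$node_var, -1L)
  pred <- hforest:::.hf_predict(tree$flat, matrix(1, 5, 3))$value
  expect_equal(length(unique(pred)), 1L)
  est <- tree$est_idx
  expect_equal(pred[1], sum(y[est] * z[est]) / sum(z[est]^2))
})

test_that("fits, predictions and importances are seed-deterministic", {
  g <- generate_sample(small_config(n_households = 300), seed = 23)
  f1 <- suppressMessages(fit_causal_forest(g$sample, "y1",
                                           params = quick_params(40),
                                           seed = 11))
  f2 <- suppressMessages(fit_causal_forest(g$sample, "y1",
                                           params = quick_params(40),
                                           seed = 11))
  expect_identical(f1$predictions, f2$predictions)
  expect_identical(f1$forest$node_thr, f2$forest$node_thr)
  expect_identical(variable_importance(f1), variable_importance(f2))
})

test_that("variable importance is a distribution that finds the driver", {
  cfg <- small_config(n_households = 1200, noise_sd = 0.5,
                      effect = list(type = "step", covariate = "white",
                                    value_in = 4, value_out = 0))
  hits <- 0
  for (r in 1:5) {
    g <- generate_sample(cfg, seed = 40 + r)
    fit <- suppressMessages(fit_causal_forest(g$sample, "y1",
                                              params = quick_params(100),
                                              seed = r))
    imp <- variable_importance(fit)
    expect_true(all(imp >= 0))
    expect_equal(sum(imp), 1, tolerance = 1e-12)
    if (names(which.max(imp)) == "white") hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("a splitless forest reports uniform importance with a warning", {
  set.seed(21)
  n <- 60
  X <- matrix(1, n, 4)
  Z <- rbinom(n, 1, 0.5)
  fit <- causal_forest(X, rnorm(n), Z,
                       params = quick_params(5, min_node_size = 2), seed = 1)
  expect_warning(imp <- variable_importance(fit), "no splits")
  expect_equal(unname(imp), rep(0.25, 4))
})

test_that("the forest summary bundles the doubly robust ATE and the
           calibration diagnostic", {
  g <- generate_sample(small_config(n_households = 400), seed = 24)
  fit <- suppressMessages(fit_causal_forest(g$sample, "y1",
                                            params = quick_params(60),
                                            seed = 13))
  sm <- summary(fit)
  expect_s3_class(sm$ate, "effect_estimate")
  expect_s3_class(sm$calibration, "calibration_result")
  expect_equal(sm$ate$estimate,
               average_effect(suppressMessages(aipw_scores(fit)))$estimate)
  expect_output(print(sm), "ATE")
})

test_that("rows without out-of-bag nuisances are dropped with a message", {
  set.seed(22)
  n <- 80
  X <- matrix(rbinom(n * 3, 1, 0.5), n, 3)
  Z <- rbinom(n, 1, 0.5)
  Y <- rnorm(n)
  expect_message(
    suppressWarnings(
      fit <- causal_forest(X, Y, Z,
                           params = quick_params(3, min_node_size = 2),
                           seed = 2)),
    "out-of-bag")
  expect_equal(nrow(fit$X), length(fit$kept))
  expect_true(all(!is.na(fit$nuisance$m_hat)))
})
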