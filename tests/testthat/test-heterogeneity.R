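test_that("calibration is near one for a well-specified heterogeneous forest
           and flags constant predictions", {
  cfg <- small_config(
    n_households = 1500, noise_sd = 1,
    effect = list(type = "linear",
                  coefs = c(intercept = 1, depression = 2)))
  g <- generate_sample(cfg, seed = 51)
  fit <- suppressMessages(fit_causal_forest(g$sample, "y1",
                                            params = quick_params(200),
                                            seed = 12))
  cal <- calibration_test(fit)
  expect_true(cal$beta_estimable)
  expect_lt(abs(cal$alpha - 1), 3 * cal$se_alpha)
  expect_true(cal$p_beta >= 0 && cal$p_beta <= 1)

  # constant out-of-bag CATEs: beta not estimable, alpha still returned
  fit2 <- fit
  fit2$predictions <- rep(0.7, length(fit$predictions))
  cal2 <- calibration_test(fit2)
  expect_false(cal2$beta_estimable)
  expect_true(is.na(cal2$beta))
  expect_true(is.finite(cal2$alpha))
})

test_that("the cross-fitted calibration test detects real heterogeneity,
           is deterministic, and calibrates the mean prediction", {
  cfg <- small_config(n_households = 1500, noise_sd = 1,
                      effect = list(type = "step", covariate = "white",
                                    value_in = 3, value_out = 1))
  g <- generate_sample(cfg, seed = 55)
  cal1 <- calibration_test_crossfit(g$sample, "y1",
                                    params = quick_params(150, mtry = 8),
                                    seed = 7)
  cal2 <- calibration_test_crossfit(g$sample, "y1",
                                    params = quick_params(150, mtry = 8),
                                    seed = 7)
  expect_identical(cal1$beta, cal2$beta)
  expect_true(cal1$beta_estimable)
  expect_lt(cal1$p_beta, 0.05)
  expect_lt(abs(cal1$alpha - 1), 3 * cal1$se_alpha)
})

test_that("a constant priority yields a flat TOC and zero rate", {
  n <- 100
  sc <- compute_aipw_scores(Y = rnorm(n), Z = rbinom(n, 1, 0.5),
                            m_hat = rep(0, n), e_hat = rep(0.5, n),
                            tau_hat = rep(0, n))
  expect_warning(curve <- toc_curve(sc, rep(1, n)), "ties")
  expect_true(all(abs(curve$toc) < 1e-10))
  expect_lt(abs(curve$rate), 1e-10)
})

test_that("an oracle priority on a two-group population gives the
           closed-form TOC", {
  n <- 400
  gamma <- c(rep(3, n / 2), rep(1, n / 2))
  sc <- structure(
    data.frame(gamma = gamma, weight = rep(1, n), household = seq_len(n)),
    outcome = "y", class = c("aipw_scores", "data.frame"))
  curve <- suppressWarnings(toc_curve(sc, priority = gamma))
  expect_equal(curve$toc[curve$q_grid == 0.5], 3 - 2, tolerance = 1e-10)
  expect_equal(curve$toc[curve$q_grid == 1], 0, tolerance = 1e-10)
  expect_gt(curve$rate, 0)
  # reversing the priority flips the curve on this symmetric population
  rev_curve <- suppressWarnings(toc_curve(sc, priority = -gamma))
  expect_equal(rev_curve$toc[rev_curve$q_grid == 0.5], -1,
               tolerance = 1e-10)
  expect_equal(rev_curve$rate, -curve$rate, tolerance = 1e-10)
  # with uniform rank weights the area statistic tracks the mean TOC value
  expect_lt(abs(curve$rate - mean(curve$toc)), 0.05)
  # Qini weighting remains sign-consistent
  qini <- suppressWarnings(toc_curve(sc, priority = gamma,
                                     method = "qini"))
  expect_gt(qini$rate, 0)
})

test_that("the split-based RATE is deterministic, near zero under
           homogeneity, and positive under strong two-group targeting", {
  cfg0 <- small_config(n_households = 600,
                       effect = list(type = "constant", value = 1))
  g0 <- generate_sample(cfg0, seed = 53)
  r1 <- suppressMessages(rate_with_se(g0$sample, "y1",
                                      params = quick_params(80),
                                      n_half_splits = 4, seed = 5))
  r2 <- suppressMessages(rate_with_se(g0$sample, "y1",
                                      params = quick_params(80),
                                      n_half_splits = 4, seed = 5))
  expect_identical(r1$rates, r2$rates)
  expect_lt(abs(r1$rate), 3 * max(r1$se_rate, 1e-3) + 0.15)

  cfg1 <- small_config(n_households = 1500, noise_sd = 0.5,
                       effect = list(type = "step", covariate = "white",
                                     value_in = 3, value_out = 1))
  g1 <- generate_sample(cfg1, seed = 54)
  rs <- suppressMessages(rate_with_se(g1$sample, "y1",
                                      params = quick_params(100),
                                      n_half_splits = 4, seed = 6))
  expect_gt(rs$rate, 0)
  expect_error(rate_with_se(g1$sample, "y1", n_half_splits = 1),
               "at least 2")
})
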