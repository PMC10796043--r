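test_that("identical config and seed reproduce the sample exactly", {
  cfg <- small_config(n_households = 200)
  g1 <- generate_sample(cfg, seed = 11)
  g2 <- generate_sample(cfg, seed = 11)
  expect_identical(as.data.frame(g1$sample), as.data.frame(g2$sample))
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_sample(cfg, seed = 12)
  expect_false(identical(g1$sample$y_y1, g3$sample$y_y1))
})

test_that("generated samples satisfy the design invariants", {
  cfg <- small_config(n_households = 2500, crossover = 0.02)
  g <- generate_sample(cfg, seed = 5)
  s <- g$sample
  expect_silent(validate_sample(s))
  # lottery is a household-level draw
  expect_true(all(tapply(s$Z, s$household_id,
                         function(z) length(unique(z))) == 1))
  # funnel ordering
  expect_true(all(s$applied[s$approved == 1] == 1))
  expect_true(all(s$applied[s$Z == 0] == 0))
  # crossover rate among controls within 3 binomial SEs
  n0 <- sum(s$Z == 0)
  p0 <- mean(s$D[s$Z == 0])
  expect_lt(abs(p0 - 0.02), 3 * sqrt(0.02 * 0.98 / n0))
  # funnel consistency: P(D|Z=1) = P(apply|Z=1) * P(approve|applied)
  z1 <- s$Z == 1
  p_uptake <- mean(s$D[z1])
  p_chain <- mean(s$applied[z1]) * mean(s$approved[s$applied == 1])
  expect_lt(abs(p_uptake - p_chain),
            3 * sqrt(p_chain * (1 - p_chain) / sum(z1)))
  # lognormal weights normalized to mean one
  expect_true(all(s$weight > 0))
  expect_equal(mean(s$weight), 1, tolerance = 1e-10)
})

test_that("intercept-only funnel reproduces the product of stage rates", {
  cfg <- small_config(n_households = 10000, crossover = 0,
                      apply_int = qlogis(0.64), approve_int = qlogis(0.478))
  g <- generate_sample(cfg, seed = 21)
  s <- g$sample
  z1 <- s$Z == 1
  target <- 0.64 * 0.478
  expect_lt(abs(mean(s$D[z1]) - target),
            3 * sqrt(target * (1 - target) / sum(z1)))
})

test_that("default covariate prevalences match their specification", {
  g <- generate_sample(dgp_config(n_households = 20000), seed = 31)
  X <- covariate_matrix(g$sample)
  expect_lt(abs(mean(X[, "female"]) - 0.56), 0.02)
  expect_lt(abs(mean(X[, "race_white"]) - 0.69), 0.02)
  expect_lt(abs(mean(X[, "depression"]) - 0.34), 0.02)
  expect_equal(ncol(X), 19)
})

test_that("zero effect with zero crossover forces controls out of coverage", {
  cfg <- small_config(n_households = 100, crossover = 0,
                      effect = list(type = "constant", value = 0))
  g <- generate_sample(cfg, seed = 1)
  expect_true(all(g$sample$D[g$sample$Z == 0] == 0))
  expect_true(all(g$truth$tau == 0))
})

test_that("true_cate evaluates constant, step and linear effects", {
  cfg <- small_config()
  X <- matrix(c(1, 0, 0, 1), 2, 2,
              dimnames = list(NULL, c("white", "depression")))
  cfg$effect_spec$y1 <- list(type = "constant", value = 2)
  expect_equal(true_cate(cfg, X, "y1"), c(2, 2))
  cfg$effect_spec$y1 <- list(type = "step", covariate = "white",
                             value_in = 1, value_out = 3)
  expect_equal(true_cate(cfg, X, "y1"), c(1, 3))
  cfg$effect_spec$y1 <- list(type = "linear",
                             coefs = c(intercept = 0.5, depression = 2))
  expect_equal(true_cate(cfg, X, "y1"), 0.5 + 2 * X[, "depression"])
  cfg$effect_spec$y1 <- list(type = "linear",
                             coefs = c(intercept = 0, nonexistent = 1))
  expect_error(true_cate(cfg, X, "y1"), "unknown covariates")
})

test_that("configuration errors name the offending field", {
  expect_error(small_config(crossover = 1.5), "control_crossover")
  expect_error(
    dgp_config(covariate_spec = list(
      bad = list(type = "binary", p = 1.2))), "bad")
  expect_error(
    dgp_config(household_size_probs = c(0.5, 0.4)), "household_size_probs")
  cfg <- small_config()
  expect_error(
    dgp_config(covariate_spec = small_covariates(),
               apply_coefs = c(intercept = 0, ghost = 1),
               approve_coefs = c(intercept = 0),
               outcome_specs = cfg$outcome_specs,
               effect_spec = cfg$effect_spec),
    "ghost")
})

test_that("true effects drive outcomes through the configured channel", {
  # treatment channel: effect loads on D, so ITT is attenuated by compliance
  cfg_t <- small_config(n_households = 4000, crossover = 0, noise_sd = 0.5,
                        apply_int = 0, approve_int = 20,
                        effect = list(type = "constant", value = 2))
  cfg_t$effect_channel <- "treatment"
  g <- generate_sample(cfg_t, seed = 3)
  s <- g$sample
  itt <- mean(s$y_y1[s$Z == 1]) - mean(s$y_y1[s$Z == 0])
  compliance <- mean(s$D[s$Z == 1])
  expect_lt(abs(itt - 2 * compliance), 0.15)
  expect_lt(abs(compliance - 0.5), 0.05)
})
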