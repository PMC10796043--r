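test_that("under perfect compliance the instrumental forest reduces to the
           causal forest", {
  cfg <- small_config(n_households = 300, crossover = 0,
                      apply_int = 20, approve_int = 20)
  g <- generate_sample(cfg, seed = 29)
  s <- g$sample
  expect_identical(s$D, s$Z)
  cf <- suppressMessages(fit_causal_forest(s, "y1",
                                           params = quick_params(80),
                                           seed = 6))
  ivf <- suppressMessages(fit_instrumental_forest(s, "y1",
                                                  params = quick_params(80),
                                                  seed = 6))
  keep <- !is.na(cf$predictions) & !is.na(ivf$predictions)
  expect_gt(mean(keep), 0.9)
  expect_equal(ivf$predictions[keep], cf$predictions[keep],
               tolerance = 1e-9)
  Xq <- covariate_matrix(s)[1:20, ]
  expect_equal(as.numeric(predict(ivf, newdata = Xq)),
               as.numeric(predict(cf, newdata = Xq)), tolerance = 1e-9)
})

test_that("one-sided noncompliance recovers the complier effect", {
  cfg <- small_config(n_households = 3200, crossover = 0, noise_sd = 1,
                      apply_int = 0, approve_int = 20,
                      effect = list(type = "constant", value = 2))
  cfg$effect_channel <- "treatment"
  g <- generate_sample(cfg, seed = 31)
  s <- g$sample
  compliance <- mean(s$D[s$Z == 1])
  expect_lt(abs(compliance - 0.5), 0.05)

  ivf <- suppressMessages(fit_instrumental_forest(s, "y1",
                                                  params = quick_params(300),
                                                  seed = 7))
  tau_iv <- ivf$predictions
  # complier-effect scale: kernel-averaged IV predictions sit near 2 while
  # the intent-to-treat effect is attenuated to about compliance * 2 = 1
  fy <- suppressMessages(fit_causal_forest(s, "y1",
                                           params = quick_params(300),
                                           seed = 8))
  fd <- suppressMessages(fit_causal_forest(s, "D",
                                           params = quick_params(300),
                                           seed = 9))
  sy <- suppressMessages(aipw_scores(fy))
  sd_ <- suppressMessages(aipw_scores(fd))
  common <- intersect(fy$sample$person_id[!is.na(fy$predictions)],
                      fd$sample$person_id[!is.na(fd$predictions)])
  align <- function(sc, fit) {
    ids <- fit$sample$person_id[!is.na(fit$predictions)]
    out <- sc[match(common, ids), , drop = FALSE]
    class(out) <- c("aipw_scores", "data.frame")
    attr(out, "outcome") <- attr(sc, "outcome")
    out
  }
  itt <- average_effect(align(sy, fy))
  late <- late_effect(align(sy, fy), align(sd_, fd))
  expect_lt(abs(late$estimate - 2), 3 * late$se)
  expect_lt(abs(itt$estimate - 1), 3 * itt$se)
  expect_lt(abs(mean(tau_iv, na.rm = TRUE) - 2), 0.35)
})

test_that("instrumental fits validate their inputs", {
  set.seed(33)
  X <- matrix(rbinom(200, 1, 0.5), 100, 2)
  Z <- rbinom(100, 1, 0.5)
  expect_error(instrumental_forest(X, rnorm(100), D = Z * 2, Z = Z,
                                   params = quick_params(5)),
               "binary")
})
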