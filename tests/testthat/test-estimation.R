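test_that("AIPW scores reproduce direct arithmetic and exact-nuisance limits", {
  # single-person arithmetic: m(x,1) = 2, m(x,0) = 1, Y = 3, e = 0.5
  sc <- compute_aipw_scores(Y = 3, Z = 1, m_hat = 1.5, e_hat = 0.5,
                            tau_hat = 1, households = 1)
  expect_equal(sc$gamma, 1 + (3 - 2) * 0.5 / 0.25)

  # noiseless outcomes with exact nuisances: gamma_i = tau(X_i) exactly
  set.seed(41)
  n <- 200
  x <- rbinom(n, 1, 0.5)
  Z <- rbinom(n, 1, 0.5)
  tau <- 1 + 2 * x
  mu <- 3 * x
  e <- rep(0.5, n)
  Y <- mu + Z * tau
  m <- mu + e * tau
  sc <- compute_aipw_scores(Y, Z, m, e, tau)
  expect_equal(sc$gamma, tau, tolerance = 1e-12)
})

test_that("with trivial nuisances the score mean is the weighted
           difference in means", {
  set.seed(42)
  n <- 100
  Z <- rep(c(0, 1), n / 2)
  Y <- rnorm(n)
  w <- runif(n, 0.5, 2)
  # force identical total weight in both arms so the algebra is exact
  w[Z == 1] <- w[Z == 1] * sum(w[Z == 0]) / sum(w[Z == 1])
  sc <- compute_aipw_scores(Y, Z, m_hat = rep(0, n), e_hat = rep(0.5, n),
                            tau_hat = rep(0, n), weights = w)
  dim_hand <- weighted.mean(Y[Z == 1], w[Z == 1]) -
    weighted.mean(Y[Z == 0], w[Z == 0])
  expect_equal(sum(sc$weight * sc$gamma) / sum(sc$weight), dim_hand,
               tolerance = 1e-12)
})

test_that("the cluster-robust average matches an independent sandwich fit", {
  # six persons in three households, unequal weights
  gamma <- c(1.2, 0.8, 2.5, -0.3, 0.9, 1.4)
  w <- c(1, 2, 0.5, 1.5, 1, 3)
  hh <- c(1, 1, 2, 2, 3, 3)
  sc <- structure(data.frame(gamma = gamma, weight = w, household = hh),
                  outcome = "y", class = c("aipw_scores", "data.frame"))
  est <- average_effect(sc)
  expect_equal(est$estimate, sum(w * gamma) / sum(w))
  # oracle route: weighted intercept-only regression with HC0 cluster vcov
  fit <- stats::lm(gamma ~ 1, weights = w)
  V <- sandwich::vcovCL(fit, cluster = hh, type = "HC0", cadjust = FALSE)
  expect_equal(est$se, sqrt(V[1, 1]), tolerance = 1e-10)
  expect_equal(est$ci_low, est$estimate - 1.96 * est$se)
  expect_equal(est$n_households, 3L)

  # all-constant scores have zero variance
  sc2 <- compute_aipw_scores(Y = rep(1, 4), Z = c(0, 1, 0, 1),
                             m_hat = rep(0.5, 4), e_hat = rep(0.5, 4),
                             tau_hat = rep(1, 4),
                             households = c(1, 1, 2, 2))
  sc2$gamma <- rep(2, 4)
  est2 <- average_effect(sc2)
  expect_equal(est2$estimate, 2)
  expect_equal(est2$se, 0)
})

test_that("subgroup effects recombine exactly and reject empty masks", {
  set.seed(43)
  n <- 300
  sc <- compute_aipw_scores(Y = rnorm(n), Z = rbinom(n, 1, 0.5),
                            m_hat = rep(0, n), e_hat = rep(0.5, n),
                            tau_hat = rep(0, n),
                            weights = runif(n, 0.5, 3),
                            households = rep(1:100, 3))
  ate <- average_effect(sc)
  mask <- rbinom(n, 1, 0.4) == 1
  gA <- group_average_effect(sc, mask, "A")
  gB <- group_average_effect(sc, !mask, "B")
  shareA <- sum(sc$weight[mask]) / sum(sc$weight)
  expect_equal(shareA * gA$estimate + (1 - shareA) * gB$estimate,
               ate$estimate, tolerance = 1e-10)
  expect_identical(group_average_effect(sc, rep(TRUE, n))$estimate,
                   ate$estimate)
  expect_error(group_average_effect(sc, rep(FALSE, n), "ghosts"), "ghosts")
})

test_that("effects are exactly scale equivariant", {
  set.seed(44)
  n <- 60
  sc <- compute_aipw_scores(Y = rnorm(n), Z = rbinom(n, 1, 0.5),
                            m_hat = rep(0, n), e_hat = rep(0.5, n),
                            tau_hat = rep(0.3, n),
                            households = rep(1:20, 3))
  e1 <- average_effect(sc)
  sc$gamma <- 7 * sc$gamma
  e7 <- average_effect(sc)
  expect_equal(e7$estimate, 7 * e1$estimate)
  expect_equal(e7$se, 7 * e1$se)
  expect_equal(e7$ci_high, 7 * e1$ci_high)
})

test_that("a single household cannot support a cluster-robust SE", {
  sc <- compute_aipw_scores(Y = c(1, 2), Z = c(0, 1), m_hat = c(0, 0),
                            e_hat = c(0.5, 0.5), tau_hat = c(0, 0),
                            households = c(1, 1))
  expect_error(average_effect(sc), "single household")
})

test_that("the complier-effect ratio behaves at its trivial limits", {
  set.seed(45)
  n <- 80
  hh <- rep(1:40, 2)
  mk <- function(g) {
    structure(data.frame(gamma = g, weight = rep(1, n), household = hh),
              outcome = "y", class = c("aipw_scores", "data.frame"))
  }
  sy <- mk(rnorm(n))
  # unit first stage: the complier effect equals the intent-to-treat effect
  late <- late_effect(sy, mk(rep(1, n)))
  itt <- average_effect(sy)
  expect_equal(late$estimate, itt$estimate)
  expect_equal(late$se, itt$se, tolerance = 1e-12)
  # zero numerator: zero effect with a finite delta-method SE
  l0 <- late_effect(mk(rep(0, n)), mk(rnorm(n) + 1))
  expect_equal(l0$estimate, 0)
  expect_gte(l0$se, 0)
  # weak instrument
  expect_error(late_effect(sy, mk(rep(0, n))), "weak instrument")
})

test_that("standardized differences match closed forms", {
  v <- c(rep(1, 60), rep(0, 40), rep(1, 40), rep(0, 60))
  g <- rep(c(1, 0), each = 100)
  expect_equal(standardized_difference(v, g),
               0.2 / sqrt((0.24 + 0.24) / 2), tolerance = 1e-12)
  expect_equal(standardized_difference(rep(c(0, 1), 50),
                                       rep(c(0, 1), each = 50)), 0,
               tolerance = 1e-12)
  # continuous values use pooled weighted variances
  set.seed(46)
  x <- rnorm(200)
  grp <- rep(c(0, 1), 100)
  sd_hand <- abs(mean(x[grp == 1]) - mean(x[grp == 0])) /
    sqrt((stats::var(x[grp == 1]) * 99 / 100 +
            stats::var(x[grp == 0]) * 99 / 100) / 2)
  expect_equal(standardized_difference(x, grp), sd_hand, tolerance = 1e-12)
  expect_error(standardized_difference(x, rep(1, 200)), "nonempty")
})

test_that("the balance table covers every covariate of a sample", {
  g <- generate_sample(small_config(n_households = 400), seed = 47)
  bt <- balance_table(g$sample)
  expect_equal(sort(bt$covariate),
               sort(sub("^x_", "", attr(g$sample, "covariates"))))
  expect_true(all(bt$std_diff >= 0))
  # randomization keeps imbalance small
  expect_lt(max(bt$std_diff), 0.25)
})
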