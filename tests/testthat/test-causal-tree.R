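test_that("the grown first split matches the brute-force criterion maximizer", {
  for (r in 1:60) {
    inst <- random_split_instance(r)
    tree <- grow_single_tree(inst$X, inst$y, inst$z, inst$w, inst$treated,
                             min_node_size = 2, alpha = 0.05, seed = r)
    best <- oracle_best_split(inst$X, inst$y, inst$z, inst$w, inst$treated,
                              tree$split_idx, tree$est_idx,
                              min_node_size = 2, alpha = 0.05)
    if (is.null(best)) {
      expect_equal(tree$flat$node_var[1], -1L,
                   label = sprintf("instance %d: grown split", r))
    } else {
      expect_equal(tree$flat$node_var[1] + 1L, best$var,
                   label = sprintf("instance %d: split covariate", r))
      expect_equal(tree$flat$node_thr[1], best$thr,
                   label = sprintf("instance %d: split threshold", r))
    }
  }
})

test_that("constant covariates give a single-leaf tree with the ratio estimate", {
  set.seed(7)
  n <- 40
  X <- matrix(1, n, 2)
  z <- rep(c(0, 1), n / 2) - 0.5
  treated <- as.integer(z > 0)
  y <- rnorm(n)
  w <- runif(n, 0.5, 2)
  tree <- grow_single_tree(X, y, z, w, treated, min_node_size = 2, seed = 1)
  expect_equal(tree$flat$node_var, -1L)
  est <- tree$est_idx
  expect_equal(tree$flat$leaf_value[1],
               sum(w[est] * y[est] * z[est]) / sum(w[est] * z[est]^2))
})

test_that("a noiseless two-group effect is split out and estimated exactly", {
  set.seed(8)
  n <- 64
  x1 <- rep(c(0, 1), each = n / 2)
  X <- cbind(x1 = x1, noise = rbinom(n, 1, 0.5))
  Z <- rep(c(0, 1), n / 2)
  z <- Z - 0.5
  tau <- ifelse(x1 == 1, 2, -2)
  y <- tau * z   # exactly centered, zero noise
  tree <- grow_single_tree(X, y, z, rep(1, n), Z, min_node_size = 2,
                           seed = 2)
  expect_equal(tree$flat$node_var[1], 0L)   # splits on x1
  leaves <- tree$flat$node_var == -1L
  vals <- tree$flat$leaf_value[leaves & tree$flat$leaf_cnt > 0]
  expect_true(all(abs(abs(vals) - 2) < 1e-6))
})

test_that("splits depend only on the splitting half (honesty)", {
  inst <- random_split_instance(99)
  tree1 <- grow_single_tree(inst$X, inst$y, inst$z, inst$w, inst$treated,
                            min_node_size = 2, seed = 5)
  y2 <- inst$y
  y2[tree1$est_idx[1]] <- y2[tree1$est_idx[1]] + 100
  tree2 <- grow_single_tree(inst$X, y2, inst$z, inst$w, inst$treated,
                            min_node_size = 2, seed = 5)
  expect_identical(tree1$flat$node_var, tree2$flat$node_var)
  expect_identical(tree1$flat$node_thr, tree2$flat$node_thr)
  expect_identical(tree1$flat$node_left, tree2$flat$node_left)
})

test_that("households enter each tree's subsample as complete units", {
  cfg <- small_config(n_households = 150)
  cfg$household_size_probs <- c(0.2, 0.8, 0)   # mostly two-person households
  g <- generate_sample(cfg, seed = 9)
  s <- g$sample
  fit <- suppressMessages(fit_causal_forest(
    s, "y1", params = quick_params(40, sample_fraction = 0.5), seed = 1))
  flat <- fit$forest
  # every member of a household shares the in-bag/out-of-bag status, so the
  # out-of-bag tree count must be constant within household
  used <- fit$oob_trees_used
  per_hh <- tapply(used, fit$clusters, function(u) length(unique(u)))
  expect_true(all(per_hh == 1))
  # in-bag household lists never contain duplicates
  for (b in seq_len(flat$n_trees)) {
    idx <- (flat$inbag_offset[b] + 1):flat$inbag_offset[b + 1]
    expect_false(anyDuplicated(flat$inbag_hh[idx]) > 0)
  }
})

test_that("degenerate estimation-half denominators inherit the parent estimate", {
  # one leaf-forcing configuration: all treated share one covariate level so
  # a child can end with Z-residual variation but no weight on one arm
  set.seed(10)
  n <- 24
  X <- cbind(x1 = rep(c(0, 1), each = n / 2))
  Z <- c(rep(0, n / 2), rep(1, n / 2))   # treatment confounded with x1
  z <- Z - 0.5
  y <- rnorm(n)
  tree <- grow_single_tree(X, y, z, rep(1, n), Z, min_node_size = 2,
                           seed = 3)
  # no admissible split exists (children would be single-arm), so the root
  # stays a leaf with a valid pooled estimate
  expect_equal(tree$flat$node_var, -1L)
  expect_equal(tree$flat$leaf_inherit[1], 0L)
})
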