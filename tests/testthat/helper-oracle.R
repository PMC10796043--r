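# Independent plain-R implementation of the causal split criterion, used as
# a brute-force oracle against the compiled tree growth.  Mirrors the
# documented criterion: survey-weighted within-leaf ratio estimators and
# variances, unweighted outer counts, alpha-imbalance and estimation-half
# node-size constraints, lowest-covariate then lowest-threshold tie-breaks.

oracle_crit <- function(idx, y, z, w, treated, Ntr, Nest) {
  den <- sum(w[idx] * z[idx]^2)
  ti <- idx[treated[idx] == 1]
  ci <- idx[treated[idx] == 0]
  sw_t <- sum(w[ti]); sw_c <- sum(w[ci])
  if (abs(den) < 1e-12 || sw_t <= 0 || sw_c <= 0) return(NA_real_)
  tau <- sum(w[idx] * z[idx] * y[idx]) / den
  p <- sw_t / (sw_t + sw_c)
  wvar <- function(ii) {
    m <- sum(w[ii] * y[ii]) / sum(w[ii])
    max(sum(w[ii] * y[ii]^2) / sum(w[ii]) - m^2, 0)
  }
  V <- wvar(ti) / p + wvar(ci) / (1 - p)
  length(idx) * tau^2 / Ntr - (1 / Ntr + 1 / Nest) * V
}

# exhaustive search over every covariate and every midpoint threshold;
# returns list(var, thr, gain) or NULL when no admissible improving split
oracle_best_split <- function(X, y, z, w, treated, split_idx, est_idx,
                              min_node_size, alpha, penalty = 0) {
  ns <- length(split_idx)
  Ntr <- max(1, ns)
  Nest <- max(1, length(est_idx))
  par_crit <- oracle_crit(split_idx, y, z, w, treated, Ntr, Nest)
  if (is.na(par_crit) || ns < 2) return(NULL)
  minside <- max(1, ceiling(alpha * ns))
  best <- NULL
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[split_idx, j]))
    if (length(xs) < 2) next
    thrs <- (head(xs, -1) + tail(xs, -1)) / 2
    for (thr in thrs) {
      L <- split_idx[X[split_idx, j] <= thr]
      R <- setdiff(split_idx, L)
      if (length(L) < minside || length(R) < minside) next
      eL <- est_idx[X[est_idx, j] <= thr]
      eR <- setdiff(est_idx, eL)
      ok_est <- function(e) {
        sum(treated[e] == 1) >= min_node_size &&
          sum(treated[e] == 0) >= min_node_size
      }
      if (!ok_est(eL) || !ok_est(eR)) next
      cl <- oracle_crit(L, y, z, w, treated, Ntr, Nest)
      cr <- oracle_crit(R, y, z, w, treated, Ntr, Nest)
      if (is.na(cl) || is.na(cr)) next
      gain <- cl + cr - par_crit - penalty * (1 / length(L) + 1 / length(R))
      if (gain > 0 && (is.null(best) || gain > best$gain)) {
        best <- list(var = j, thr = thr, gain = gain)
      }
    }
  }
  best
}

# grow a single honest causal tree on given residualized data through the
# compiled engine, with every row its own household and the full sample in
# bag; returns the flat forest plus the realized honesty halves
grow_single_tree <- function(X, y, z, w, treated, min_node_size = 2,
                             alpha = 0.05, penalty = 0, seed = 1,
                             type = 1L, d = NULL) {
  n <- nrow(X)
  storage.mode(X) <- "double"
  flat <- hforest:::.hf_grow_forest(
    X, as.numeric(y), as.numeric(z),
    if (is.null(d)) numeric(n) else as.numeric(d),
    as.integer(treated), as.numeric(w), 0:(n - 1), n, as.integer(type), 1L,
    1.0, 0.5, ncol(X), as.integer(min_node_size), alpha, penalty,
    as.integer(seed))
  est_idx <- sort(unique(flat$est_rows)) + 1L
  list(flat = flat, est_idx = est_idx,
       split_idx = setdiff(seq_len(n), est_idx))
}

# random small instance for the oracle comparison
random_split_instance <- function(r) {
  set.seed(r)
  n <- sample(16:30, 1)
  p <- sample(1:3, 1)
  X <- matrix(0, n, p)
  for (j in seq_len(p)) {
    X[, j] <- if (runif(1) < 0.5) {
      rbinom(n, 1, runif(1, 0.3, 0.7))
    } else {
      round(runif(n), 2)
    }
  }
  treated <- rbinom(n, 1, 0.5)
  while (sum(treated) < 3 || sum(1 - treated) < 3) {
    treated <- rbinom(n, 1, 0.5)
  }
  list(X = X, y = rnorm(n), z = treated - 0.5, w = runif(n, 0.5, 2),
       treated = treated)
}
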